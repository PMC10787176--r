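# Promoter chromatin-state analysis. Promoters are TSS -2 kb / +1 kb,
# strand-aware; a promoter overlapping a chromHMM state segment by >= 1 bp
# is annotated by that state. Interval arithmetic is delegated to
# IRanges/GenomicRanges; all external coordinates stay 0-based half-open
# (BED convention) and are converted at the boundary.

#' Strand-aware promoter intervals
#'
#' For a + strand gene with TSS t the promoter is
#' `[t - upstream, t + downstream)`; for a - strand gene the window is
#' reflected so that "upstream" follows the direction of transcription:
#' `[t - downstream + 1, t + upstream + 1)`. On both strands the TSS base
#' itself belongs to the downstream side. Intervals are clipped at 0.
#'
#' @param annotation A [gene_annotation()] with TSS and strand.
#' @param upstream,downstream Window sizes in bp (2000/1000 by
#'   convention).
#' @return A data.frame: gene_id, chromosome, start, end (0-based
#'   half-open).
#' @export
promoter_intervals <- function(annotation, upstream = 2000L,
                               downstream = 1000L) {
  t <- annotation$tss
  plus <- annotation$strand == "+"
  start <- ifelse(plus, t - upstream, t - downstream + 1L)
  end <- ifelse(plus, t + downstream, t + upstream + 1L)
  start <- pmax(start, 0L)
  data.frame(gene_id = annotation$gene_id,
             chromosome = annotation$chromosome,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Intersect promoters with a chromatin-state segmentation
#'
#' A promoter is annotated by every state it overlaps by at least
#' `min_overlap` bases in the given epigenome; overlapped base counts are
#' accumulated per gene and state.
#'
#' @param promoters Output of [promoter_intervals()].
#' @param segmentation A `chrom_segmentation` (see [read_segmentation()]).
#' @param min_overlap Minimum overlap in bases (default 1).
#' @return A data.frame: gene_id, state, bases, epigenome_id.
#' @export
intersect_states <- function(promoters, segmentation, min_overlap = 1L) {
  iv <- segmentation$intervals
  if (!nrow(iv) || !nrow(promoters))
    return(data.frame(gene_id = character(), state = character(),
                      bases = integer(), epigenome_id = character(),
                      stringsAsFactors = FALSE))
  # 0-based half-open -> 1-based closed for IRanges
  pr <- GenomicRanges::GRanges(promoters$chromosome,
                               IRanges::IRanges(promoters$start + 1L,
                                                promoters$end))
  sr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end))
  hits <- GenomicRanges::findOverlaps(pr, sr, minoverlap = min_overlap)
  if (!length(hits))
    return(data.frame(gene_id = character(), state = character(),
                      bases = integer(), epigenome_id = character(),
                      stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(pr)[qi],
                                           IRanges::ranges(sr)[si]))
  keep <- ov >= min_overlap
  d <- data.frame(gene_id = promoters$gene_id[qi[keep]],
                  state = iv$state[si[keep]], bases = ov[keep],
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(bases ~ gene_id + state, d, sum)
  agg$epigenome_id <- segmentation$epigenome_id
  agg
}

#' Promoter state profiles across many epigenomes
#'
#' @param promoters Output of [promoter_intervals()].
#' @param segmentations List of `chrom_segmentation` objects.
#' @param min_overlap Minimum overlap in bases.
#' @return A data.frame: gene_id, state, bases, epigenome_id (one row per
#'   gene/state/epigenome combination with overlap).
#' @export
state_profiles <- function(promoters, segmentations, min_overlap = 1L) {
  do.call(rbind, lapply(segmentations, function(s)
    intersect_states(promoters, s, min_overlap)))
}

#' Promoter state diversity: X vs autosomes
#'
#' Per gene, the number of distinct chromatin states over all epigenomes
#' (`mode = "distinct"`, the default) or the sum of per-epigenome distinct
#' counts (`mode = "sum"`); class medians are compared by the rank-sum
#' test.
#'
#' @param profiles Output of [state_profiles()].
#' @param annotation A [gene_annotation()].
#' @param mode Counting mode, see above.
#' @param x_chrom X chromosome label(s).
#' @return A list: `per_gene` (gene_id, n_states, is_x), `median_x`,
#'   `median_a`, `p` (rank-sum), `n_epigenomes`.
#' @export
state_diversity <- function(profiles, annotation,
                            mode = c("distinct", "sum"), x_chrom = "X") {
  mode <- match.arg(mode)
  counts <- if (mode == "distinct") {
    tapply(profiles$state, profiles$gene_id,
           function(s) length(unique(s)))
  } else {
    tapply(paste(profiles$epigenome_id, profiles$state), profiles$gene_id,
           function(s) length(unique(s)))
  }
  per_gene <- data.frame(gene_id = names(counts),
                         n_states = as.integer(counts),
                         stringsAsFactors = FALSE)
  per_gene$is_x <- is_x_gene(annotation, x_chrom)[
    match(per_gene$gene_id, annotation$gene_id)]
  vx <- per_gene$n_states[per_gene$is_x]
  va <- per_gene$n_states[!per_gene$is_x]
  wt <- if (length(vx) && length(va)) ranksum_compare(vx, va)
  else list(p = NA_real_)
  list(per_gene = per_gene,
       median_x = if (length(vx)) stats::median(vx) else NA_real_,
       median_a = if (length(va)) stats::median(va) else NA_real_,
       p = wt$p,
       n_epigenomes = length(unique(profiles$epigenome_id)))
}

#' Per-chromosome state base fractions
#'
#' Fraction of annotated promoter bases in each state, per chromosome,
#' summed over all epigenomes; fractions within a chromosome sum to 1.
#' Chromosomes with no annotated bases are omitted.
#'
#' @param profiles Output of [state_profiles()].
#' @param annotation A [gene_annotation()].
#' @return A data.frame: chromosome, state, bases, fraction.
#' @export
state_base_fraction <- function(profiles, annotation) {
  profiles$chromosome <- annotation$chromosome[
    match(profiles$gene_id, annotation$gene_id)]
  agg <- stats::aggregate(bases ~ chromosome + state, profiles, sum)
  totals <- tapply(agg$bases, agg$chromosome, sum)
  agg$fraction <- agg$bases / as.numeric(totals[agg$chromosome])
  agg[order(agg$chromosome, -agg$fraction), , drop = FALSE]
}
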