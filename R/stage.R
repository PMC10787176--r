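# Stage-correlated gene analysis: per-gene Spearman correlation between
# expression and developmental-stage rank within a tissue, classification
# into positively/negatively correlated sets, the X-linked enrichment
# sweep over correlation thresholds, and the testis-enrichment Fisher test.

#' Per-gene Spearman correlation with developmental stage
#'
#' Within one tissue each gene has a series of expression values over
#' samples ordered by `stage_rank` (young to old). Replicates within a
#' stage share a rank; ties are handled by average ranks. p-values are
#' exact (permutation enumeration) for at most 9 samples and use the t
#' approximation otherwise. Genes with constant expression have undefined
#' rho and are reported with missing values.
#'
#' @param x An [expr_matrix()].
#' @param tissue Tissue to analyse (needs >= 4 samples with stage ranks).
#' @param exact_limit Largest sample count for exact permutation p-values.
#' @return A data.frame: gene_id, chromosome, rho, p, n_samples.
#' @export
stage_correlation <- function(x, tissue, exact_limit = 9L) {
  s <- x$samples[x$samples$tissue == tissue, , drop = FALSE]
  if (nrow(s) < 4L) stop("need >= 4 samples with stage ranks in ", tissue)
  E <- x$E[, s$sample_id, drop = FALSE]
  yr <- rank(s$stage_rank)
  n <- length(yr)
  Xr <- t(apply(E, 1L, rank))
  sx <- apply(Xr, 1L, stats::sd)
  rho <- rep(NA_real_, nrow(E))
  ok <- sx > 0 & stats::sd(yr) > 0
  if (any(ok))
    rho[ok] <- as.vector((Xr[ok, , drop = FALSE] %*% yr - n * rowMeans(
      Xr[ok, , drop = FALSE]) * mean(yr)) / ((n - 1) * sx[ok] * stats::sd(yr)))
  p <- rep(NA_real_, nrow(E))
  if (n <= exact_limit) {
    p <- spearman_exact_batch(Xr, yr)
  } else {
    r2 <- pmin(rho[ok]^2, 1 - 1e-15)
    tt <- rho[ok] * sqrt((n - 2) / (1 - r2))
    p[ok] <- pmax(2 * stats::pt(-abs(tt), n - 2), .Machine$double.xmin)
  }
  data.frame(gene_id = rownames(E),
             chromosome = x$genes$chromosome[match(rownames(E),
                                                   x$genes$gene_id)],
             rho = rho, p = p, n_samples = n, stringsAsFactors = FALSE)
}

#' Classify stage-correlated genes
#'
#' Positive: rho > `rho_threshold` and p < `p_threshold`; negative:
#' rho < -`rho_threshold` and p < `p_threshold` (raw p-values by
#' convention; set `adjust = "BH"` for a Benjamini-Hochberg variant).
#'
#' @param results Output of [stage_correlation()].
#' @param rho_threshold Absolute correlation threshold (default 0.8).
#' @param p_threshold Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list: `positive` and `negative` gene-id vectors (disjoint).
#' @export
classify_stage_correlated <- function(results, rho_threshold = 0.8,
                                      p_threshold = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(results$p, "BH") else results$p
  ok <- !is.na(results$rho) & !is.na(p)
  list(
    positive = results$gene_id[ok & results$rho > rho_threshold &
                                 p < p_threshold],
    negative = results$gene_id[ok & results$rho < -rho_threshold &
                                 p < p_threshold]
  )
}

#' X-linked fraction of stage-correlated genes across thresholds
#'
#' For each correlation threshold and trend sign, the fraction of
#' classified genes that are X-linked, against the baseline X-linked share
#' among all analysed genes. Classified sets are nested: the set at a
#' stricter threshold is a subset of that at a looser one.
#'
#' @param results Output of [stage_correlation()].
#' @param thresholds Ascending correlation thresholds.
#' @param p_threshold Significance threshold held fixed across the sweep.
#' @param x_chrom X chromosome label(s).
#' @param denominator `"classified"` (fraction among classified genes,
#'   default) or `"all"` (classified X genes over all X genes, vs the same
#'   for autosomes).
#' @return A data.frame: threshold, sign, n_classified, fraction_x,
#'   baseline_fraction_x.
#' @export
xlinked_fraction_by_threshold <- function(results,
                                          thresholds = seq(0.5, 0.9, 0.1),
                                          p_threshold = 0.05,
                                          x_chrom = "X",
                                          denominator = c("classified",
                                                          "all")) {
  denominator <- match.arg(denominator)
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  is_x <- results$chromosome %in% x_chrom
  baseline <- mean(is_x)
  rows <- list()
  for (th in thresholds) {
    cls <- classify_stage_correlated(results, th, p_threshold)
    for (sgn in c("positive", "negative")) {
      ids <- cls[[sgn]]
      in_set <- results$gene_id %in% ids
      frac <- if (denominator == "classified") {
        if (length(ids)) mean(is_x[in_set]) else NA_real_
      } else {
        fx <- if (sum(is_x)) sum(in_set & is_x) / sum(is_x) else 0
        fx
      }
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, sign = sgn, n_classified = length(ids),
        fraction_x = frac, baseline_fraction_x = baseline,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tissue-preference enrichment test for a chromosome class
#'
#' Fisher's exact test of whether X-linked genes are enriched among genes
#' whose maximum expression falls in a given tissue (e.g. testis).
#'
#' @param assignment Output of [max_tissue_assignment()].
#' @param annotation A [gene_annotation()].
#' @param tissue Tissue tested for enrichment.
#' @param x_chrom X chromosome label(s).
#' @return As [fisher_exact()], plus the 2x2 `table`.
#' @export
tissue_enrichment_test <- function(assignment, annotation, tissue,
                                   x_chrom = "X") {
  is_x <- is_x_gene(annotation, x_chrom)[match(assignment$gene_id,
                                               annotation$gene_id)]
  in_t <- assignment$max_tissue == tissue
  tab <- matrix(c(sum(is_x & in_t), sum(is_x & !in_t),
                  sum(!is_x & in_t), sum(!is_x & !in_t)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("X", "autosome"),
                                c(tissue, paste0("not_", tissue))))
  res <- fisher_exact(tab)
  res$table <- tab
  res
}
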