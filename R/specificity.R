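# Tau specificity. For a profile x_1..x_n over n contexts,
#   tau = sum_i (1 - x_i / max_j x_j) / (n - 1),
# ranging from 0 (broadly expressed) to 1 (single-context expression).
# Applied over tissues (tissue specificity, profile = per-tissue mean FPKM
# across a tissue's stages) and over stages within a tissue
# (developmental-stage specificity). Because tissues cover different
# numbers of sampled stages, stage-specificity values are not comparable
# across tissues.

#' Tau specificity index of one expression profile
#'
#' @param profile Non-negative numeric vector of expression levels over
#'   n >= 2 contexts (tissues or stages).
#' @return Tau in [0, 1].
#' @export
tau <- function(profile) {
  stopifnot(is.numeric(profile))
  if (length(profile) < 2L) stop("tau needs at least two contexts")
  if (any(profile < 0)) stop("expression must be non-negative")
  m <- max(profile)
  if (m == 0) stop("all-zero profile: gene must be excluded from tau")
  sum(1 - profile / m) / (length(profile) - 1L)
}

#' Per-gene mean expression by tissue
#'
#' Cell (g, t) is the arithmetic mean of gene g over all samples of tissue
#' t (i.e. throughout that tissue's developmental stages).
#'
#' @param x An [expr_matrix()].
#' @return Numeric matrix genes x tissues.
#' @export
tissue_mean_expression <- function(x) {
  tissues <- sort(unique(x$samples$tissue))
  out <- vapply(tissues, function(t)
    rowMeans(x$E[, x$samples$tissue == t, drop = FALSE]),
    numeric(nrow(x$E)))
  colnames(out) <- tissues
  out
}

#' Tau tissue specificity for all genes
#'
#' Genes expressed in no tissue (all-zero profiles) are excluded.
#'
#' @param x An [expr_matrix()], or a precomputed gene x tissue matrix.
#' @param log_transform Apply log2(x + 1) before tau (off by default; the
#'   convention here is raw mean FPKM).
#' @return A data.frame: gene_id, tau_tissue.
#' @export
tissue_specificity <- function(x, log_transform = FALSE) {
  tbl <- if (inherits(x, "expr_matrix")) tissue_mean_expression(x) else x
  if (log_transform) tbl <- log2(tbl + 1)
  keep <- rowSums(tbl) > 0
  if (any(!keep)) xd_log(sum(!keep), " all-zero gene(s) excluded from tau")
  tbl <- tbl[keep, , drop = FALSE]
  tv <- apply(tbl, 1L, tau)
  data.frame(gene_id = rownames(tbl), tau_tissue = unname(tv),
             stringsAsFactors = FALSE)
}

#' Developmental-stage specificity within one tissue
#'
#' Per-stage expression is the mean over that stage's replicates; tau is
#' computed over the stage vector. All-zero genes are excluded. Values are
#' not comparable across tissues (different stage coverage).
#'
#' @param x An [expr_matrix()].
#' @param tissue Tissue to analyse.
#' @param log_transform Apply log2(x + 1) before tau.
#' @return A data.frame: gene_id, tau_stage, n_stages.
#' @export
stage_specificity <- function(x, tissue, log_transform = FALSE) {
  s <- x$samples[x$samples$tissue == tissue, , drop = FALSE]
  if (!nrow(s)) stop("no samples for tissue ", tissue)
  stages <- sort(unique(s$stage_rank))
  if (length(stages) < 2L) stop("need at least two stages in ", tissue)
  tbl <- vapply(stages, function(st)
    rowMeans(x$E[, s$sample_id[s$stage_rank == st], drop = FALSE]),
    numeric(nrow(x$E)))
  if (log_transform) tbl <- log2(tbl + 1)
  keep <- rowSums(tbl) > 0
  tbl <- tbl[keep, , drop = FALSE]
  data.frame(gene_id = rownames(x$E)[keep],
             tau_stage = unname(apply(tbl, 1L, tau)),
             n_stages = length(stages), stringsAsFactors = FALSE)
}

#' Assign each gene to its maximum-expression tissue
#'
#' Ties are broken by the first tissue in sorted order and flagged.
#' All-zero genes are excluded.
#'
#' @param tbl Gene x tissue matrix from [tissue_mean_expression()].
#' @return A data.frame: gene_id, max_tissue, tie.
#' @export
max_tissue_assignment <- function(tbl) {
  tbl <- tbl[, sort(colnames(tbl)), drop = FALSE]
  keep <- rowSums(tbl) > 0
  tbl <- tbl[keep, , drop = FALSE]
  idx <- apply(tbl, 1L, which.max)
  n_max <- rowSums(tbl == tbl[cbind(seq_len(nrow(tbl)), idx)])
  data.frame(gene_id = rownames(tbl), max_tissue = colnames(tbl)[idx],
             tie = n_max > 1L, stringsAsFactors = FALSE)
}

#' Tissue-specific gene sets and X-linked fractions
#'
#' A gene is tissue-specific iff its tau exceeds `tau_threshold`; it is
#' assigned to its maximum-expression tissue. Reports, per tissue, the
#' specific-gene count and the fraction of those genes that are X-linked.
#'
#' @param x An [expr_matrix()].
#' @param tau_threshold Specificity threshold (0.8 is the conventional
#'   value; exposed because the literature varies).
#' @param x_chrom X chromosome label(s).
#' @param log_transform Passed to [tissue_specificity()].
#' @return A list: `genes` (gene_id, tau_tissue, max_tissue, specific,
#'   is_x) and `by_tissue` (tissue, n_specific, n_specific_x, frac_x).
#' @export
tissue_specific_genes <- function(x, tau_threshold = 0.8, x_chrom = "X",
                                  log_transform = FALSE) {
  tbl <- tissue_mean_expression(x)
  tt <- tissue_specificity(tbl, log_transform = log_transform)
  mt <- max_tissue_assignment(tbl)
  g <- merge(tt, mt, by = "gene_id", sort = FALSE)
  g$specific <- g$tau_tissue > tau_threshold
  g$is_x <- is_x_gene(x$genes, x_chrom)[match(g$gene_id, x$genes$gene_id)]
  sp <- g[g$specific, , drop = FALSE]
  tissues <- sort(colnames(tbl))
  by_tissue <- data.frame(
    tissue = tissues,
    n_specific = vapply(tissues, function(t) sum(sp$max_tissue == t),
                        integer(1L)),
    n_specific_x = vapply(tissues, function(t)
      sum(sp$max_tissue == t & sp$is_x), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  by_tissue$frac_x <- ifelse(by_tissue$n_specific > 0,
                             by_tissue$n_specific_x / by_tissue$n_specific,
                             NA_real_)
  list(genes = g, by_tissue = by_tissue)
}

#' Correlation between X:AA ratios and X-linked specific-gene fractions
#'
#' Spearman rank correlation across the tissues common to both inputs.
#'
#' @param ratios Named numeric vector: tissue -> X:AA ratio.
#' @param fractions Named numeric vector: tissue -> X-linked fraction of
#'   tissue-specific genes.
#' @return A list: `rho`, `p`, `n_tissues`.
#' @export
ratio_vs_specific_fraction <- function(ratios, fractions) {
  common <- intersect(names(ratios), names(fractions))
  if (length(common) < 3L) stop("need at least 3 common tissues")
  st <- spearman_test(as.numeric(ratios[common]),
                      as.numeric(fractions[common]))
  list(rho = st$rho, p = st$p, n_tissues = length(common))
}
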