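# X:AA ratio engine. The estimator is the ratio of means fixed by the
# Methods convention ("ratio of mean expression level of X-linked genes to
# that of autosomal genes"), not the mean of per-gene ratios — the two
# differ under the heavy right skew of FPKM. Filtering at the expression
# cutoff is applied per context (tissue/stage) before computing means.

ratio_estimate <- function(context, cutoff, ratio, ci_low = NA_real_,
                           ci_high = NA_real_, n_x = NA_integer_,
                           n_a = NA_integer_) {
  data.frame(context = context, cutoff = cutoff, ratio = ratio,
             ci_low = ci_low, ci_high = ci_high, n_x = n_x, n_a = n_a,
             stringsAsFactors = FALSE)
}

# Filtered per-class context values; shared by the point ratio and the
# bootstrap. Returns list(x = numeric, a = numeric).
xaa_values <- function(x, samples = NULL, cutoff = 1, strict = TRUE,
                       x_chrom = "X") {
  v <- context_values(x, samples)
  keep <- if (is.finite(cutoff)) {
    if (strict) v > cutoff else v >= cutoff
  } else rep(TRUE, length(v))
  xg <- is_x_gene(x$genes, x_chrom)
  ag <- is_autosomal_gene(x$genes)
  list(x = v[keep & xg], a = v[keep & ag])
}

#' X:AA expression point ratio
#'
#' Mean expression of X-linked genes divided by mean expression of
#' autosomal genes in one context, after retaining genes above the
#' expression cutoff (FPKM > 1 by convention; `cutoff = -Inf` retains all
#' genes).
#'
#' @param x An [expr_matrix()].
#' @param tissue,stage_label Optional context filters (see
#'   [select_samples()]); per-gene expression is the mean over the selected
#'   samples.
#' @param samples Explicit sample ids overriding the tissue/stage filters.
#' @param cutoff Expression cutoff; genes with value > cutoff are retained
#'   (`strict = FALSE` uses >=).
#' @param strict Filter convention, see [filter_expressed()].
#' @param x_chrom Chromosome label(s) counted as X.
#' @return A one-row data.frame: context, cutoff, ratio, ci_low, ci_high
#'   (NA here), n_x, n_a.
#' @export
xaa_ratio <- function(x, tissue = NULL, stage_label = NULL, samples = NULL,
                      cutoff = 1, strict = TRUE, x_chrom = "X") {
  samples <- samples %||% select_samples(x, tissue, stage_label)
  ctx <- context_label(tissue, stage_label)
  vals <- xaa_values(x, samples, cutoff, strict, x_chrom)
  if (!length(vals$x))
    stop("no X-linked genes above cutoff ", cutoff, " in context ", ctx)
  if (!length(vals$a))
    stop("no autosomal genes above cutoff ", cutoff, " in context ", ctx)
  ratio_estimate(ctx, cutoff, mean(vals$x) / mean(vals$a),
                 n_x = length(vals$x), n_a = length(vals$a))
}

#' X:AA ratio with a size-matched bootstrap confidence interval
#'
#' For each of `n_boot` replicates, a set of autosomal genes equal in
#' number to the filtered X-linked set is drawn (without replacement by
#' default) and the replicate ratio mean(X)/mean(sampled A) computed; the
#' X set is held fixed, so the interval describes the sampling variability
#' of the autosomal reference. CI bounds are nearest-rank empirical
#' percentiles at `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @inheritParams xaa_ratio
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level (0.90 by convention).
#' @param seed Integer seed; identical seeds give bit-identical intervals.
#' @param replace Sample autosomal genes with replacement (sensitivity
#'   option; the size-matched subsampling default matches the stated
#'   resampling scheme).
#' @return A one-row data.frame as in [xaa_ratio()] with CI bounds filled.
#' @export
bootstrap_xaa <- function(x, tissue = NULL, stage_label = NULL,
                          samples = NULL, cutoff = 1, strict = TRUE,
                          n_boot = 1000L, level = 0.90, seed = 1L,
                          replace = FALSE, x_chrom = "X") {
  est <- xaa_ratio(x, tissue, stage_label, samples, cutoff, strict, x_chrom)
  samples <- samples %||% select_samples(x, tissue, stage_label)
  vals <- xaa_values(x, samples, cutoff, strict, x_chrom)
  n_x <- length(vals$x); n_a <- length(vals$a)
  if (!replace && n_a < n_x)
    stop("fewer autosomal than X-linked genes after filtering (",
         n_a, " < ", n_x, "); cannot subsample without replacement")
  mx <- mean(vals$x)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i)
      mx / mean(sample(vals$a, n_x, replace = replace)), numeric(1L))
  })
  alpha <- (1 - level) / 2
  est$ci_low <- nearest_rank(reps, alpha)
  est$ci_high <- nearest_rank(reps, 1 - alpha)
  attr(est, "replicates") <- reps
  est
}

#' X:AA ratios over a series of expression cutoffs
#'
#' One estimate per cutoff, ascending, with an optional all-genes sentinel
#' (no filter, reported with cutoff `-Inf` and context suffix "all"). The
#' cutoff-0 entry retains genes with value > 0, the "zero" cutoff
#' convention. A cutoff at which a chromosome class empties is recorded as
#' a missing (NA) ratio rather than an error.
#'
#' @inheritParams bootstrap_xaa
#' @param cutoffs Ascending numeric cutoffs, typically within [0, 1].
#' @param include_all_genes Append the unfiltered sentinel entry.
#' @param boot Also compute bootstrap CIs per cutoff.
#' @return A data.frame with one row per cutoff.
#' @export
ratio_cutoff_series <- function(x, tissue = NULL, stage_label = NULL,
                                samples = NULL,
                                cutoffs = c(0, 0.25, 0.5, 0.75, 1),
                                include_all_genes = TRUE, boot = FALSE,
                                n_boot = 1000L, level = 0.90, seed = 1L,
                                x_chrom = "X") {
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  cuts <- as.numeric(cutoffs)
  if (include_all_genes) cuts <- c(-Inf, cuts)
  out <- lapply(cuts, function(ct) {
    tryCatch(
      if (boot) bootstrap_xaa(x, tissue, stage_label, samples, ct,
                              n_boot = n_boot, level = level, seed = seed,
                              x_chrom = x_chrom)
      else xaa_ratio(x, tissue, stage_label, samples, ct, x_chrom = x_chrom),
      error = function(e)
        ratio_estimate(context_label(tissue, stage_label), ct, NA_real_))
  })
  res <- do.call(rbind, out)
  res$cutoff_label <- vapply(res$cutoff, function(ct)
    if (is.finite(ct)) format(ct) else "all", character(1L))
  res
}

#' Expression ratios against housekeeping-gene references
#'
#' Housekeeping genes (HKGs) are constitutively expressed references:
#' `x_to_ahkg` tracks the expression of all X-linked genes against
#' autosomal HKGs, while `xhkg_to_ahkg` compares the two HKG subsets and
#' stays flat when compensation is stable.
#'
#' @inheritParams xaa_ratio
#' @param ahkg_ids,xhkg_ids Autosomal / X-linked housekeeping gene ids.
#' @return One-row data.frame: context, cutoff, x_to_ahkg, xhkg_to_ahkg
#'   and the per-set gene counts.
#' @export
hkg_ratios <- function(x, ahkg_ids, xhkg_ids, tissue = NULL,
                       stage_label = NULL, samples = NULL, cutoff = 1,
                       strict = TRUE, x_chrom = "X") {
  samples <- samples %||% select_samples(x, tissue, stage_label)
  ctx <- context_label(tissue, stage_label)
  v <- context_values(x, samples)
  keep <- if (is.finite(cutoff)) {
    if (strict) v > cutoff else v >= cutoff
  } else rep(TRUE, length(v))
  ids <- names(v)
  v_x <- v[keep & is_x_gene(x$genes, x_chrom)]
  v_ahkg <- v[keep & ids %in% ahkg_ids]
  v_xhkg <- v[keep & ids %in% xhkg_ids]
  if (!length(v_ahkg)) stop("AHKG set empty after filtering in ", ctx)
  if (!length(v_xhkg)) stop("XHKG set empty after filtering in ", ctx)
  if (!length(v_x)) stop("no X-linked genes after filtering in ", ctx)
  data.frame(context = ctx, cutoff = cutoff,
             x_to_ahkg = mean(v_x) / mean(v_ahkg),
             xhkg_to_ahkg = mean(v_xhkg) / mean(v_ahkg),
             n_x = length(v_x), n_ahkg = length(v_ahkg),
             n_xhkg = length(v_xhkg), stringsAsFactors = FALSE)
}

#' Fraction of unexpressed genes per chromosome class
#'
#' Genes with value <= cutoff are defined as unexpressed. Reports the
#' per-class fraction and the X-over-autosome fold enrichment (NA when the
#' autosomal fraction is 0).
#'
#' @inheritParams xaa_ratio
#' @return A data.frame with rows for classes "X" and "autosomes" plus the
#'   fold in column `fold_x_over_a` (repeated on both rows).
#' @export
unexpressed_fraction <- function(x, tissue = NULL, stage_label = NULL,
                                 samples = NULL, cutoff = 1, x_chrom = "X") {
  samples <- samples %||% select_samples(x, tissue, stage_label)
  v <- context_values(x, samples)
  xg <- is_x_gene(x$genes, x_chrom)
  ag <- is_autosomal_gene(x$genes)
  if (!sum(xg) || !sum(ag)) stop("need at least one gene per class")
  fx <- mean(v[xg] <= cutoff)
  fa <- mean(v[ag] <= cutoff)
  fold <- if (fa > 0) fx / fa else NA_real_
  data.frame(context = context_label(tissue, stage_label), cutoff = cutoff,
             chromosome_class = c("X", "autosomes"), fraction = c(fx, fa),
             n_genes = c(sum(xg), sum(ag)), fold_x_over_a = fold,
             stringsAsFactors = FALSE)
}

#' Combine X:AA ratios from multiple data sources
#'
#' When several datasets cover the same tissue, the tissue's ratio is the
#' arithmetic mean of the per-source ratios.
#'
#' @param ratios_by_source Named list mapping tissue to a numeric vector of
#'   per-source ratios.
#' @return Named numeric vector of combined per-tissue ratios.
#' @export
combine_ratio_sources <- function(ratios_by_source) {
  stopifnot(is.list(ratios_by_source), length(names(ratios_by_source)) ==
              length(ratios_by_source))
  vapply(ratios_by_source, function(r) {
    if (!length(r)) stop("empty ratio list for a tissue")
    mean(as.numeric(r))
  }, numeric(1L))
}
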