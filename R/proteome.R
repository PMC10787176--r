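# Proteome bin matching. Mass-spectrometry coverage and resolution limit
# per-gene comparisons, so X-linked and autosomal protein abundances are
# separately split into quantile bins (100 by convention) and only the
# top-abundance bins (25 by convention) are compared bin against bin.

#' Quantile bins of protein abundances for one chromosome class
#'
#' Genes are sorted by descending abundance (ties broken by gene id for
#' determinism) and split into `n_bins` contiguous groups of near-equal
#' size; when sizes cannot be equal the remainder r goes to the first r
#' (highest-abundance) bins.
#'
#' @param abundances Named numeric vector (names = gene ids) of iBAQ-like
#'   abundances for one class.
#' @param n_bins Number of bins (requires at least `n_bins` genes).
#' @return A data.frame: bin_index (1 = highest abundance), n_genes,
#'   bin_mean; gene membership in attribute `"members"`.
#' @export
quantile_bins <- function(abundances, n_bins = 100L) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)))
  n <- length(abundances)
  if (n < n_bins)
    stop("only ", n, " genes for ", n_bins,
         " bins; use a smaller n_bins")
  ord <- order(-abundances, names(abundances))
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  members <- split(names(abundances)[ord], bin)
  means <- vapply(split(abundances[ord], bin), mean, numeric(1L))
  out <- data.frame(bin_index = seq_len(n_bins), n_genes = sizes,
                    bin_mean = unname(means))
  attr(out, "members") <- members
  out
}

#' Bin-matched X:AA ratio at the proteome level
#'
#' For the `top_k` highest-abundance bins, ratio_i = X bin mean / autosome
#' bin mean; the summary is the median (or mean) over the k per-bin
#' ratios. A zero autosomal bin mean yields a missing ratio for that bin.
#'
#' @param x_bins,a_bins Outputs of [quantile_bins()] for the X-linked and
#'   autosomal classes.
#' @param top_k Number of top bins compared (default 25).
#' @param summary `"median"` (default) or `"mean"`.
#' @return A list: `per_bin` (bin_index, x_mean, a_mean, ratio) and
#'   `summary` (the median/mean over the k ratios).
#' @export
bin_matched_ratio <- function(x_bins, a_bins, top_k = 25L,
                              summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (nrow(x_bins) < top_k || nrow(a_bins) < top_k)
    stop("both bin tables need at least ", top_k, " bins")
  xb <- x_bins$bin_mean[seq_len(top_k)]
  ab <- a_bins$bin_mean[seq_len(top_k)]
  ratio <- ifelse(ab > 0, xb / ab, NA_real_)
  per_bin <- data.frame(bin_index = seq_len(top_k), x_mean = xb,
                        a_mean = ab, ratio = ratio)
  s <- if (summary == "median") stats::median(ratio, na.rm = TRUE)
  else mean(ratio, na.rm = TRUE)
  list(per_bin = per_bin, summary = s)
}

#' Proteome X:AA bin comparison for one context
#'
#' Convenience wrapper: extracts per-gene abundances in the context, bins
#' the X-linked and autosomal classes separately, compares the top bins
#' and attaches a rank-sum test between the two sets of compared bin
#' means.
#'
#' @param x A protein-abundance [expr_matrix()].
#' @param tissue,samples Context selection as in [xaa_ratio()].
#' @param n_bins,top_k Binning parameters.
#' @param x_chrom X chromosome label(s).
#' @return As [bin_matched_ratio()], plus `wilcoxon` (see
#'   [ranksum_compare()]).
#' @export
proteome_bin_comparison <- function(x, tissue = NULL, samples = NULL,
                                    n_bins = 100L, top_k = 25L,
                                    x_chrom = "X") {
  samples <- samples %||% select_samples(x, tissue)
  v <- context_values(x, samples)
  xg <- is_x_gene(x$genes, x_chrom)
  ag <- is_autosomal_gene(x$genes)
  xb <- quantile_bins(v[xg], n_bins)
  ab <- quantile_bins(v[ag], n_bins)
  res <- bin_matched_ratio(xb, ab, top_k)
  res$wilcoxon <- ranksum_compare(res$per_bin$x_mean, res$per_bin$a_mean)
  res
}
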