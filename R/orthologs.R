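# Cross-species ortholog ratios. The proto-X is unobservable; its
# expression is proxied by the autosomal 1:1 orthologs of current X-linked
# genes in an outgroup that diverged before the sex chromosomes originated
# (chicken-like: orthologs of the X sit on chr1/chr4). The pipeline order
# is fixed: filter -> scale -> normalize -> median.

#' Classify ortholog pairs into X and AA comparison classes
#'
#' An X pair has its focal gene on the X chromosome and its outgroup
#' ortholog on an allowed outgroup autosome (`allowed_x_chroms`; an empty
#' set accepts any autosome). An AA pair has an autosomal focal gene whose
#' ortholog is not on an excluded outgroup chromosome (typically the
#' outgroup's own sex chromosomes, e.g. Z/W). Marsupial-style rules are
#' supported via `treat_outgroup_x_as_autosome`: the outgroup X (which is
#' biallelically up-regulated in the opossum) is treated as an ordinary
#' pair of autosomes. Pairs fitting neither class are dropped with a
#' logged count.
#'
#' @param map An [ortholog_map()].
#' @param allowed_x_chroms Outgroup chromosomes accepted for X pairs
#'   (character; empty = any autosome).
#' @param excluded_chroms Outgroup chromosomes excluded from AA pairs.
#' @param outgroup_sex_chroms Labels counted as outgroup sex chromosomes.
#' @param treat_outgroup_x_as_autosome Treat outgroup "X" as an autosome.
#' @param x_chrom Focal X chromosome label(s).
#' @return The map with a `pair_class` column (`"X_pair"`/`"AA_pair"`),
#'   unclassifiable pairs removed.
#' @export
classify_pairs <- function(map, allowed_x_chroms = character(),
                           excluded_chroms = c("Z", "W"),
                           outgroup_sex_chroms = c("X", "Y", "Z", "W"),
                           treat_outgroup_x_as_autosome = FALSE,
                           x_chrom = "X") {
  d <- as.data.frame(map)
  sex <- outgroup_sex_chroms
  if (treat_outgroup_x_as_autosome) sex <- setdiff(sex, "X")
  out_autosomal <- !(d$outgroup_chrom %in% c(sex, "MT", "M"))
  focal_x <- d$focal_chrom %in% x_chrom
  x_ok <- if (length(allowed_x_chroms))
    d$outgroup_chrom %in% allowed_x_chroms else out_autosomal
  is_x_pair <- focal_x & x_ok & out_autosomal
  is_aa_pair <- !focal_x & !(d$focal_chrom %in% c("X", "Y", "MT", "M")) &
    !(d$outgroup_chrom %in% excluded_chroms) & out_autosomal
  cls <- ifelse(is_x_pair, "X_pair", ifelse(is_aa_pair, "AA_pair", NA))
  n_drop <- sum(is.na(cls))
  if (n_drop) xd_log(n_drop, " ortholog pair(s) fit neither class; dropped")
  d$pair_class <- cls
  d <- d[!is.na(cls), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("paired_expression", "data.frame")
  d
}

#' Attach per-context expression values to classified pairs
#'
#' @param pairs Output of [classify_pairs()].
#' @param focal,outgroup [expr_matrix()] objects for the two species.
#' @param tissue,stage_label Context filters applied to both species
#'   (per-gene value = mean over the selected samples).
#' @return The pairs with `focal_value` and `outgroup_value` columns.
#' @export
pair_expression <- function(pairs, focal, outgroup, tissue = NULL,
                            stage_label = NULL) {
  vf <- context_values(focal, select_samples(focal, tissue, stage_label))
  vo <- context_values(outgroup, select_samples(outgroup, tissue, stage_label))
  keep <- pairs$focal_gene %in% names(vf) & pairs$outgroup_gene %in% names(vo)
  if (any(!keep))
    xd_log(sum(!keep), " pair(s) without expression values dropped")
  pairs <- pairs[keep, , drop = FALSE]
  pairs$focal_value <- unname(vf[pairs$focal_gene])
  pairs$outgroup_value <- unname(vo[pairs$outgroup_gene])
  pairs
}

#' Scale outgroup expression to the focal species
#'
#' Retains pairs in which both members exceed the cutoff (the fair-
#' comparison rule: the X carries more unexpressed genes, so both species'
#' members must be expressed), then multiplies outgroup values by
#' s = median(focal)/median(outgroup) over all retained pairs (X and AA
#' pooled) so the between-species medians coincide. Focal values are
#' untouched.
#'
#' @param pairs Output of [pair_expression()].
#' @param cutoff Expression cutoff applied to both members (strict >).
#' @return The retained pairs with scaled `outgroup_value`; the factor is
#'   attached as attribute `"scale_factor"`.
#' @export
scale_between_species <- function(pairs, cutoff = 1) {
  keep <- pairs$focal_value > cutoff & pairs$outgroup_value > cutoff
  d <- pairs[keep, , drop = FALSE]
  if (!nrow(d)) stop("no ortholog pairs retained at cutoff ", cutoff)
  s <- stats::median(d$focal_value) / stats::median(d$outgroup_value)
  d$outgroup_value <- d$outgroup_value * s
  attr(d, "scale_factor") <- s
  d
}

#' X:XX and AA:AA ortholog expression ratios
#'
#' Per-pair ratios r = focal/outgroup are normalized by the median over AA
#' pairs, making the AA:AA median exactly 1 by construction; the X:XX
#' ratio is the median of the normalized ratios over X pairs. A median of
#' 0.5 signals evolutionarily halved X expression (no dosage
#' compensation); a median of 1 signals full compensation.
#'
#' @param pairs Scaled pairs from [scale_between_species()].
#' @return A list: `x_xx`, `aa_aa` (always 1), `n_x_pairs`, `n_aa_pairs`,
#'   and `ratios` (the normalized per-pair ratios with classes).
#' @export
xxx_ratio <- function(pairs) {
  if (!all(c("X_pair", "AA_pair") %in% pairs$pair_class))
    stop("need at least one X pair and one AA pair")
  r <- pairs$focal_value / pairs$outgroup_value
  norm <- stats::median(r[pairs$pair_class == "AA_pair"])
  r <- r / norm
  aa_aa <- stats::median(r[pairs$pair_class == "AA_pair"])
  list(x_xx = stats::median(r[pairs$pair_class == "X_pair"]),
       aa_aa = aa_aa,
       n_x_pairs = sum(pairs$pair_class == "X_pair"),
       n_aa_pairs = sum(pairs$pair_class == "AA_pair"),
       ratios = data.frame(focal_gene = pairs$focal_gene,
                           pair_class = pairs$pair_class, ratio = r,
                           stringsAsFactors = FALSE))
}

#' One-call X:XX pipeline for a context
#'
#' Convenience wrapper running classify -> expression -> filter/scale ->
#' normalize/median for one tissue (per-tissue scaling by default; set
#' `scale_pairs` to pre-scaled pairs to share a global factor).
#'
#' @inheritParams pair_expression
#' @inheritParams classify_pairs
#' @param map An [ortholog_map()].
#' @param cutoff Expression cutoff for both pair members.
#' @return As [xxx_ratio()].
#' @export
xxx_pipeline <- function(map, focal, outgroup, tissue = NULL,
                         stage_label = NULL, cutoff = 1,
                         allowed_x_chroms = character(),
                         excluded_chroms = c("Z", "W"),
                         outgroup_sex_chroms = c("X", "Y", "Z", "W"),
                         treat_outgroup_x_as_autosome = FALSE) {
  pairs <- classify_pairs(map, allowed_x_chroms, excluded_chroms,
                          outgroup_sex_chroms,
                          treat_outgroup_x_as_autosome)
  pairs <- pair_expression(pairs, focal, outgroup, tissue, stage_label)
  pairs <- scale_between_species(pairs, cutoff)
  xxx_ratio(pairs)
}
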