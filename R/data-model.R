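#' Construct a gene annotation table
#'
#' The annotation defines the X vs autosome partition used by every ratio.
#' Coordinates follow the BED convention: the TSS is a 0-based position.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chromosome Character chromosome labels (e.g. `"1"`..`"22"`, `"X"`).
#' @param biotype Gene biotype; ratio analyses conventionally restrict to
#'   `"protein_coding"`.
#' @param tss Non-negative integer transcription start sites (0-based).
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chromosome, biotype = "protein_coding",
                            tss = 0L, strand = "+") {
  ann <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    biotype = as.character(biotype),
    tss = as.integer(tss),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(ann$tss < 0L)) stop("tss must be non-negative")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

required_sample_cols <- c("sample_id", "species", "tissue", "stage_label",
                          "stage_rank", "sex")

#' Construct an expression matrix with gene and sample metadata
#'
#' The central container: a genes x samples grid of non-negative abundances
#' (FPKM or iBAQ) tied to a [gene_annotation()] and a sample sheet. Modelled
#' on the list-like expression containers of the microarray/RNA-seq
#' tradition: `$E` is the numeric matrix, `$genes` the annotation rows in
#' matrix order, `$samples` the sample metadata in column order.
#'
#' @param E Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param genes A [gene_annotation()] covering all rownames of `E`.
#' @param samples A data.frame with columns sample_id, species, tissue,
#'   stage_label, stage_rank, sex covering all colnames of `E`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(E, genes, samples) {
  stopifnot(is.matrix(E), is.numeric(E))
  if (is.null(rownames(E)) || is.null(colnames(E)))
    stop("E must have gene rownames and sample colnames")
  if (any(E < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (anyNA(E)) stop("expression values must not be NA")
  missing_genes <- setdiff(rownames(E), genes$gene_id)
  if (length(missing_genes))
    stop("genes not resolvable in annotation: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  miss_cols <- setdiff(required_sample_cols, names(samples))
  if (length(miss_cols))
    stop("sample sheet missing columns: ", paste(miss_cols, collapse = ", "))
  missing_samples <- setdiff(colnames(E), samples$sample_id)
  if (length(missing_samples))
    stop("samples absent from sample sheet: ",
         paste(utils::head(missing_samples, 5L), collapse = ", "))
  sex_ok <- samples$sex %in% c("male", "female", "unknown")
  if (!all(sex_ok)) stop("sex must be male, female or unknown")
  genes <- genes[match(rownames(E), genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  samples <- samples[match(colnames(E), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(E = E, genes = genes, samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n", nrow(x$E), ncol(x$E)))
  cat(sprintf("  chromosomes: %s\n",
              paste(utils::head(sort(unique(x$genes$chromosome)), 8L),
                    collapse = ", ")))
  cat(sprintf("  tissues: %s\n",
              paste(sort(unique(x$samples$tissue)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$E)

# Subset an expr_matrix by gene ids and/or sample ids, preserving order.
subset_expr <- function(x, genes = NULL, samples = NULL) {
  E <- x$E
  if (!is.null(genes)) E <- E[rownames(E) %in% genes, , drop = FALSE]
  if (!is.null(samples)) E <- E[, colnames(E) %in% samples, drop = FALSE]
  expr_matrix(E, x$genes, x$samples)
}

#' Select sample ids by tissue / stage / sex
#'
#' @param x An [expr_matrix()].
#' @param tissue,stage_label,sex Optional filters; `NULL` means no filter.
#' @param stage_rank Optional integer filter on the stage ordinal.
#' @return Character vector of sample ids (matrix column order).
#' @export
select_samples <- function(x, tissue = NULL, stage_label = NULL,
                           stage_rank = NULL, sex = NULL) {
  s <- x$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(tissue)) keep <- keep & s$tissue %in% tissue
  if (!is.null(stage_label)) keep <- keep & s$stage_label %in% stage_label
  if (!is.null(stage_rank)) keep <- keep & s$stage_rank %in% stage_rank
  if (!is.null(sex)) keep <- keep & s$sex %in% sex
  s$sample_id[keep]
}

# Per-gene expression within a context: mean over the selected samples.
# `samples = NULL` pools all samples.
context_values <- function(x, samples = NULL) {
  cols <- if (is.null(samples)) colnames(x$E) else samples
  cols <- intersect(colnames(x$E), cols)
  if (!length(cols)) stop("context selects no samples")
  rowMeans(x$E[, cols, drop = FALSE])
}

context_label <- function(tissue = NULL, stage_label = NULL) {
  lab <- c(tissue, stage_label)
  if (!length(lab)) "all-samples" else paste(lab, collapse = "/")
}

#' Filter genes by an expression cutoff
#'
#' Retains genes whose expression in the supplied context exceeds the
#' cutoff. Following the field convention, "expressed" means value > cutoff
#' (strict) and "unexpressed" value <= cutoff; `strict = FALSE` switches to
#' >= for sensitivity analyses. Gene order is preserved, so the operation is
#' idempotent and monotone in the cutoff.
#'
#' @param x An [expr_matrix()].
#' @param cutoff Non-negative expression threshold (FPKM units).
#' @param strict Logical; `TRUE` keeps value > cutoff, `FALSE` >= cutoff.
#' @param samples Optional sample ids defining the context; per-gene values
#'   are means over these columns (all columns if `NULL`).
#' @return The filtered [expr_matrix()].
#' @export
filter_expressed <- function(x, cutoff, strict = TRUE, samples = NULL) {
  stopifnot(cutoff >= 0 || !is.finite(cutoff))
  v <- context_values(x, samples)
  keep <- if (strict) v > cutoff else v >= cutoff
  subset_expr(x, genes = rownames(x$E)[keep])
}

# Chromosome-class helpers -------------------------------------------------

is_x_gene <- function(ann, x_chrom = "X") ann$chromosome %in% x_chrom

is_autosomal_gene <- function(ann, sex_chroms = c("X", "Y", "Z", "W", "MT", "M")) {
  !(ann$chromosome %in% sex_chroms)
}
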