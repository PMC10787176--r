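# Readers and writers for the plain-text dialects the pipeline exchanges:
# expression TSV (first column gene_id, remaining columns sample ids),
# sample sheet TSV, gene annotation TSV, 1:1 ortholog TSV, and 4-column
# chromHMM BED (0-based half-open).

#' Read a gene annotation TSV
#'
#' Columns: gene_id, chromosome, biotype, tss, strand.
#' @param path File path.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene_id", "chromosome", "biotype", "tss", "strand")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  gene_annotation(d$gene_id, d$chromosome, d$biotype,
                  as.integer(d$tss), d$strand)
}

#' @rdname read_gene_annotation
#' @param ann A [gene_annotation()] to write.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Columns: sample_id, species, tissue, stage_label, stage_rank, sex.
#' @param path File path.
#' @return A data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_sample_cols, names(d))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  d$stage_rank <- as.integer(d$stage_rank)
  d
}

#' @rdname read_sample_sheet
#' @param samples Sample metadata data.frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' The TSV has a header row of sample ids and a first column `gene_id`.
#' Cells must parse as non-negative decimal numbers; a malformed cell (for
#' example the literal string "NA") raises a parse error naming the gene
#' and sample. Genes present in the file but absent from the annotation are
#' dropped with a logged count; duplicated gene ids are an error. When
#' `protein_coding_only = TRUE` (the convention for dosage-compensation
#' ratios) genes of other biotypes are dropped at load time.
#'
#' @param path Expression TSV path.
#' @param annotation A [gene_annotation()].
#' @param sample_sheet Sample sheet path or data.frame.
#' @param protein_coding_only Drop non-coding genes at load time.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, annotation, sample_sheet,
                                   protein_coding_only = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (names(d)[1L] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(d$gene_id))
    stop("duplicate gene_id in expression matrix: ",
         paste(unique(d$gene_id[duplicated(d$gene_id)]), collapse = ", "))
  sample_ids <- names(d)[-1L]
  E <- matrix(NA_real_, nrow(d), length(sample_ids),
              dimnames = list(d$gene_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- d[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("cannot parse value '%s' at gene %s, sample %s",
                   raw[bad[1L]], d$gene_id[bad[1L]], sample_ids[j]))
    E[, j] <- val
  }
  unknown <- setdiff(rownames(E), annotation$gene_id)
  if (length(unknown)) {
    xd_log(length(unknown), " gene(s) absent from annotation dropped")
    E <- E[!(rownames(E) %in% unknown), , drop = FALSE]
  }
  if (protein_coding_only) {
    coding <- annotation$gene_id[annotation$biotype == "protein_coding"]
    n_drop <- sum(!(rownames(E) %in% coding))
    if (n_drop) xd_log(n_drop, " non-protein-coding gene(s) dropped")
    E <- E[rownames(E) %in% coding, , drop = FALSE]
  }
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  expr_matrix(E, annotation, sample_sheet)
}

#' Write an expression matrix TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces every double bit-exactly.
#'
#' @param x An [expr_matrix()].
#' @param path Output TSV path.
#' @export
write_expression_matrix <- function(x, path) {
  vals <- apply(x$E, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  d <- data.frame(gene_id = rownames(x$E), vals, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d) <- c("gene_id", colnames(x$E))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 1:1 ortholog map TSV
#'
#' Columns: focal_gene, outgroup_gene, focal_chrom, outgroup_chrom. Rows
#' with an empty id are dropped; a duplicated focal or outgroup id violates
#' the 1:1 relationship and is an error.
#'
#' @param path File path.
#' @return A data.frame of class `ortholog_map`.
#' @export
read_ortholog_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("focal_gene", "outgroup_gene", "focal_chrom", "outgroup_chrom")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("ortholog map missing columns: ",
                         paste(miss, collapse = ", "))
  d <- d[nzchar(d$focal_gene) & nzchar(d$outgroup_gene), , drop = FALSE]
  ortholog_map(d$focal_gene, d$outgroup_gene, d$focal_chrom, d$outgroup_chrom)
}

#' Construct a 1:1 ortholog map
#'
#' @param focal_gene,outgroup_gene Gene id vectors (each id at most once).
#' @param focal_chrom,outgroup_chrom Chromosome labels of the two members.
#' @return A data.frame of class `ortholog_map`.
#' @export
ortholog_map <- function(focal_gene, outgroup_gene, focal_chrom,
                         outgroup_chrom) {
  d <- data.frame(focal_gene = as.character(focal_gene),
                  outgroup_gene = as.character(outgroup_gene),
                  focal_chrom = as.character(focal_chrom),
                  outgroup_chrom = as.character(outgroup_chrom),
                  stringsAsFactors = FALSE)
  for (col in c("focal_gene", "outgroup_gene")) {
    dup <- unique(d[[col]][duplicated(d[[col]])])
    if (length(dup))
      stop("ortholog map is not 1:1; duplicated ", col, ": ",
           paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (!nrow(d)) xd_log("ortholog map is empty")
  class(d) <- c("ortholog_map", "data.frame")
  d
}

#' @rdname read_ortholog_map
#' @param map An `ortholog_map` to write.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a chromHMM segmentation BED
#'
#' Standard 4-column BED (chrom, start, end, state), 0-based half-open,
#' stored exactly as read. Within one epigenome, intervals on a chromosome
#' must be non-overlapping (a valid segmentation partitions the genome).
#'
#' @param path BED path.
#' @param epigenome_id Identifier for the epigenome; defaults to the file
#'   name without extension.
#' @return An object of class `chrom_segmentation`.
#' @export
read_segmentation <- function(path, epigenome_id = NULL) {
  epigenome_id <- epigenome_id %||% sub("\\.bed$", "", basename(path))
  if (file.size(path) == 0L || !length(readLines(path, n = 1L))) {
    xd_log("empty segmentation: ", path)
    d <- data.frame(chrom = character(), start = integer(),
                    end = integer(), state = character(),
                    stringsAsFactors = FALSE)
  } else {
    d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "state"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  }
  bad <- which(d$start >= d$end)
  if (length(bad))
    stop(sprintf("segmentation %s line %d: start >= end", path, bad[1L]))
  chrom_segmentation(epigenome_id, d)
}

#' Construct a chromatin segmentation
#'
#' @param epigenome_id Epigenome identifier (e.g. a Roadmap EID).
#' @param intervals data.frame with columns chrom, start, end, state
#'   (0-based half-open).
#' @return An object of class `chrom_segmentation`.
#' @export
chrom_segmentation <- function(epigenome_id, intervals) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("segmentation intervals must satisfy start < end")
  for (chr in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("overlapping segmentation intervals on chromosome ", chr)
  }
  structure(list(epigenome_id = epigenome_id,
                 intervals = intervals[order(intervals$chrom,
                                             intervals$start), , drop = FALSE]),
            class = "chrom_segmentation")
}

#' @rdname read_segmentation
#' @param seg A `chrom_segmentation` to write.
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(seg$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.chrom_segmentation <- function(x, ...) {
  cat(sprintf("chrom_segmentation %s: %d intervals on %d chromosome(s)\n",
              x$epigenome_id, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}
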