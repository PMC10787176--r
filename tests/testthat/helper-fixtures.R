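# Small in-code fixtures shared across test files.

# An expr_matrix from explicit per-gene values (one or more samples).
make_xmat <- function(values, chromosomes, sample_tissues = "brain",
                      stage_ranks = seq_along(sample_tissues),
                      gene_ids = NULL, tss = NULL, strand = "+") {
  values <- as.matrix(values)
  gene_ids <- gene_ids %||% sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- gene_ids
  sample_ids <- sprintf("s%02d", seq_len(ncol(values)))
  colnames(values) <- sample_ids
  ann <- gene_annotation(gene_ids, chromosomes,
                         tss = tss %||% (seq_len(nrow(values)) * 10000L),
                         strand = strand)
  samples <- data.frame(
    sample_id = sample_ids, species = "focal",
    tissue = rep_len(sample_tissues, ncol(values)),
    stage_label = sprintf("st%d", rep_len(stage_ranks, ncol(values))),
    stage_rank = rep_len(stage_ranks, ncol(values)), sex = "unknown",
    stringsAsFactors = FALSE)
  expr_matrix(values, ann, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_local_tempfile <- function(fileext = ".tsv")
  withr::local_tempfile(fileext = fileext, .local_envir = parent.frame())

# Quick simulated dataset at reduced size.
quick_sim <- function(seed = 1, cf = 1.0, n_a = 400L, n_x = 60L,
                      n_tissues = 2L, n_stages = 5L, ...) {
  p <- sim_params(n_autosomal_genes = n_a, n_x_genes = n_x,
                  n_tissues = n_tissues, n_stages = n_stages,
                  compensation_factor = cf, seed = seed, ...)
  ann <- simulate_genome(p)
  list(params = p, ann = ann, x = simulate_expression(ann, p))
}
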