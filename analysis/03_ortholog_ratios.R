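#!/usr/bin/env Rscript
# Cross-species X:XX and AA:AA ratios against the synthetic outgroup.
# The outgroup emulates a chicken-like species: orthologs of focal
# X-linked genes sit on its chromosomes 1 and 4, and its expression is an
# ancestral (pre-compensation) copy of the focal patterns under a global
# species scale. The pipeline is filter (both members > 1) -> median
# scaling -> AA:AA normalization -> X:XX median, per tissue.

suppressMessages(library(xdosage))

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_gene_annotation(file.path(data_dir, "genes.tsv"))
x <- read_expression_matrix(file.path(data_dir, "expression.tsv"), ann,
                            file.path(data_dir, "samples.tsv"))
og_ann <- read_gene_annotation(file.path(data_dir, "outgroup_genes.tsv"))
og <- read_expression_matrix(file.path(data_dir, "outgroup_expression.tsv"),
                             og_ann,
                             file.path(data_dir, "outgroup_samples.tsv"))
map <- read_ortholog_map(file.path(data_dir, "orthologs.tsv"))
tissues <- sort(unique(x$samples$tissue))

## chicken-like rules: X pairs must land on outgroup chr1/chr4
tab <- do.call(rbind, lapply(tissues, function(t) {
  r <- xxx_pipeline(map, x, og, tissue = t, cutoff = 1,
                    allowed_x_chroms = c("1", "4"))
  data.frame(tissue = t, x_xx = r$x_xx, aa_aa = r$aa_aa,
             n_x_pairs = r$n_x_pairs, n_aa_pairs = r$n_aa_pairs)
}))
write.table(tab, file.path(out, "xxx_ratios.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("X:XX per tissue (AA:AA median normalized to 1):\n")
print(tab, digits = 4, row.names = FALSE)
cat(sprintf("\nX:XX stays within %.3f..%.3f while the zero-cutoff X:AA",
            min(tab$x_xx), max(tab$x_xx)),
    "diverges across tissues (see 02): gene content, not compensation,\n",
    "drives the X:AA dynamics in this dataset.\n")

## per-stage X:XX in one tissue (stage-matched comparison)
stages <- sort(unique(x$samples$stage_rank))
st_tab <- do.call(rbind, lapply(stages, function(st) {
  r <- xxx_pipeline(map, x, og, stage_label = sprintf("s%02d", st),
                    cutoff = 1, allowed_x_chroms = c("1", "4"))
  data.frame(stage_rank = st, x_xx = r$x_xx, n_x_pairs = r$n_x_pairs)
}))
write.table(st_tab, file.path(out, "xxx_by_stage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nper-stage X:XX range:",
    sprintf("%.3f..%.3f\n", min(st_tab$x_xx), max(st_tab$x_xx)))
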