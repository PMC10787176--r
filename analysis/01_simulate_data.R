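#!/usr/bin/env Rscript
# Generate the synthetic study dataset used by the downstream analysis
# scripts: a focal species with full dosage compensation (X multiplier 1)
# but strongly X-biased gene content — half of the X-linked genes
# testis-specific, X-enriched stage-rising genes, excess unexpressed X
# genes — plus an outgroup species carrying the ancestral expression of
# every gene on autosomes, a proteome derived from the transcriptome, and
# 20 chromHMM-like epigenomes with larger state palettes on X promoters.
# All files are written in the plain TSV/BED dialects the loaders consume.

suppressMessages(library(xdosage))

out <- "results/data"
params <- sim_params_divergence(seed = 20260919L)

cat("simulating", params$n_autosomal_genes, "autosomal and",
    params$n_x_genes, "X-linked genes across", params$n_tissues,
    "tissues x", params$n_stages, "stages\n")
paths <- write_synthetic_dataset(out, params, n_epigenomes = 20L)

yaml::write_yaml(list(
  seed = params$seed,
  compensation_factor = params$compensation_factor,
  frac_tissue_specific_x = params$frac_tissue_specific_x,
  frac_tissue_specific_a = params$frac_tissue_specific_a,
  frac_unexpressed_x = params$frac_unexpressed_x,
  frac_unexpressed_a = params$frac_unexpressed_a,
  frac_stage_pos_x = params$frac_stage_pos_x,
  frac_stage_pos_a = params$frac_stage_pos_a,
  tissues = params$tissue_names
), file.path(out, "ground_truth.yaml"))

cat("wrote", length(paths), "dataset components under", out, "\n")
cat("ground truth: X:AA and X:XX share compensation factor",
    params$compensation_factor, "\n")
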