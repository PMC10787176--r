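# End-to-end orchestration: one config (R list or YAML file) drives the
# enabled stages in dependency order and writes TSV tables plus a
# machine-readable JSON manifest. Identical config + seed gives
# byte-identical numeric outputs; the manifest records the seed and
# per-stage row counts so any number is replayable.

pipeline_stages <- c("io", "ratios", "orthologs", "specificity", "stage",
                     "proteome", "chromatin")

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [run_full_analysis()]'s config
#'   entries (paths, cutoffs, bootstrap parameters, seed, stages,
#'   out_dir, and optionally a `synthetic` block of [sim_params()]
#'   arguments).
#' @return A config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic))
    cfg$synthetic <- do.call(sim_params, cfg$synthetic)
  cfg
}

preflight <- function(cfg) {
  stages <- cfg$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$synthetic)) {
    need <- c(expression = "expression", annotation = "annotation",
              samples = "samples")
    if ("orthologs" %in% stages)
      need <- c(need, orthologs = "orthologs",
                outgroup_expression = "outgroup_expression",
                outgroup_annotation = "outgroup_annotation",
                outgroup_samples = "outgroup_samples")
    if ("proteome" %in% stages) need <- c(need, proteome = "proteome")
    if ("chromatin" %in% stages)
      need <- c(need, segmentation_dir = "segmentation_dir")
    for (field in need)
      if (is.null(cfg[[field]]))
        stop("config field '", field, "' required for enabled stages")
    for (field in need)
      if (!file.exists(cfg[[field]]))
        stop("input path for '", field, "' does not exist: ", cfg[[field]])
  }
  stages
}

#' Run the full dosage-compensation analysis
#'
#' Executes the enabled stages in dependency order (io -> ratios ->
#' orthologs -> specificity -> stage -> proteome -> chromatin) over either
#' on-disk inputs or a synthetic dataset generated from `config$synthetic`
#' (a [sim_params()]), and writes one TSV per stage plus `manifest.json`
#' under `config$out_dir`.
#'
#' Config entries: `out_dir`; `stages` (default all); `cutoff` (default
#' 1); `n_boot` (default 1000); `level` (default 0.9); `seed` (default 1);
#' `n_epigenomes` (synthetic chromatin, default 5); input paths
#' `expression`, `annotation`, `samples`, `orthologs`,
#' `outgroup_expression`, `outgroup_annotation`, `outgroup_samples`,
#' `proteome`, `segmentation_dir` when not synthetic.
#'
#' @param config A config list or path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- preflight(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cutoff <- config$cutoff %||% 1
  n_boot <- config$n_boot %||% 1000L
  level <- config$level %||% 0.90
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, cutoff = cutoff, n_boot = n_boot,
                   level = level, stages = list(),
                   synthetic = !is.null(config$synthetic),
                   timestamp = format(Sys.time(), tz = "UTC"))

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- res
  }

  # --- io ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    params <- config$synthetic
    params$seed <- derive_seed(seed, "synthetic")
    ann <- simulate_genome(params)
    x <- simulate_expression(ann, params)
    og <- simulate_outgroup(x, params)
    prot <- simulate_proteome(x, params)
    segs <- simulate_chromatin(ann, params,
                               config$n_epigenomes %||% 5L)
    map <- og$map
    out_x <- og$expression
  } else {
    ann <- read_gene_annotation(config$annotation)
    x <- read_expression_matrix(config$expression, ann, config$samples)
    if ("orthologs" %in% stages) {
      map <- read_ortholog_map(config$orthologs)
      out_ann <- read_gene_annotation(config$outgroup_annotation)
      out_x <- read_expression_matrix(config$outgroup_expression, out_ann,
                                      config$outgroup_samples)
    }
    if ("proteome" %in% stages)
      prot <- read_expression_matrix(config$proteome, ann, config$samples)
    if ("chromatin" %in% stages)
      segs <- lapply(list.files(config$segmentation_dir, "\\.bed$",
                                full.names = TRUE), read_segmentation)
  }
  if ("io" %in% stages)
    run_stage("io", function() list(n_genes = nrow(x$E),
                                    n_samples = ncol(x$E)))

  tissues <- sort(unique(x$samples$tissue))

  # --- ratios -----------------------------------------------------------
  if ("ratios" %in% stages) run_stage("ratios", function() {
    tab <- do.call(rbind, lapply(tissues, function(t)
      cbind(tissue = t,
            bootstrap_xaa(x, tissue = t, cutoff = cutoff, n_boot = n_boot,
                          level = level,
                          seed = derive_seed(seed, paste0("boot.", t))))))
    utils::write.table(tab, file.path(out_dir, "xaa_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    series <- do.call(rbind, lapply(tissues, function(t)
      cbind(tissue = t, ratio_cutoff_series(x, tissue = t))))
    utils::write.table(series, file.path(out_dir, "xaa_cutoff_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    unexp <- do.call(rbind, lapply(tissues, function(t)
      unexpressed_fraction(x, tissue = t, cutoff = cutoff)))
    utils::write.table(unexp, file.path(out_dir, "unexpressed_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = nrow(tab) + nrow(series) + nrow(unexp))
  })

  # --- orthologs --------------------------------------------------------
  if ("orthologs" %in% stages) run_stage("orthologs", function() {
    tab <- do.call(rbind, lapply(tissues, function(t) {
      r <- xxx_pipeline(map, x, out_x, tissue = t, cutoff = cutoff)
      data.frame(tissue = t, x_xx = r$x_xx, aa_aa = r$aa_aa,
                 n_x_pairs = r$n_x_pairs, n_aa_pairs = r$n_aa_pairs)
    }))
    utils::write.table(tab, file.path(out_dir, "xxx_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = nrow(tab))
  })

  # --- specificity ------------------------------------------------------
  if ("specificity" %in% stages) run_stage("specificity", function() {
    ts <- tissue_specific_genes(x, config$tau_threshold %||% 0.8)
    utils::write.table(ts$genes, file.path(out_dir, "tau_by_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ts$by_tissue,
                       file.path(out_dir, "tissue_specific_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = nrow(ts$genes))
  })

  # --- stage ------------------------------------------------------------
  if ("stage" %in% stages) run_stage("stage", function() {
    rows <- 0L
    for (t in tissues) {
      res <- stage_correlation(x, t)
      sweep_tab <- xlinked_fraction_by_threshold(res)
      utils::write.table(res,
                         file.path(out_dir,
                                   paste0("stage_correlation_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(sweep_tab,
                         file.path(out_dir,
                                   paste0("stage_sweep_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rows <- rows + nrow(res)
    }
    list(rows = rows)
  })

  # --- proteome ---------------------------------------------------------
  if ("proteome" %in% stages) run_stage("proteome", function() {
    n_bins <- config$n_bins %||% 100L
    top_k <- config$top_k %||% 25L
    n_min <- min(sum(is_x_gene(prot$genes)),
                 sum(is_autosomal_gene(prot$genes)))
    if (n_min < n_bins) stop("too few genes for ", n_bins, " bins")
    tab <- do.call(rbind, lapply(tissues, function(t) {
      r <- proteome_bin_comparison(prot, tissue = t, n_bins = n_bins,
                                   top_k = top_k)
      cbind(tissue = t, r$per_bin,
            summary = r$summary, wilcoxon_p = r$wilcoxon$p)
    }))
    utils::write.table(tab, file.path(out_dir, "proteome_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = nrow(tab))
  })

  # --- chromatin --------------------------------------------------------
  if ("chromatin" %in% stages) run_stage("chromatin", function() {
    proms <- promoter_intervals(ann, config$upstream %||% 2000L,
                                config$downstream %||% 1000L)
    prof <- state_profiles(proms, segs)
    div <- state_diversity(prof, ann)
    utils::write.table(div$per_gene,
                       file.path(out_dir, "state_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    frac <- state_base_fraction(prof, ann)
    utils::write.table(frac, file.path(out_dir, "state_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(rows = nrow(div$per_gene), median_x = div$median_x,
         median_a = div$median_a)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
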