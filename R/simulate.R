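# Synthetic-data generator. Emulates the statistical structure the ratio
# analyses assume: log-normal FPKM with a controllable X-chromosome
# compensation factor; an outgroup species whose orthologs of focal X genes
# sit on autosomes at ancestral (pre-compensation) expression; tissue-
# specific and stage-trending gene subsets enriched/depleted per chromosome
# class; excess all-zero genes on X; a noisy proteome derived from mRNA;
# and per-epigenome chromHMM-like segmentations with larger state palettes
# on X promoters. Everything is deterministic under a fixed seed.

chromhmm_states <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk",
                     "6_EnhG", "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv",
                     "11_BivFlnk", "12_EnhBiv", "13_ReprPC", "14_ReprPCWk",
                     "15_Quies")

#' Simulation parameters
#'
#' Ground-truth parameters for the synthetic dataset. `compensation_factor`
#' is the multiplier applied to every X-linked gene relative to its own
#' ancestral expression level, so the X:AA ratio and the X:XX ratio share a
#' single ground truth; divergence between the two observables is induced
#' only through gene-content structure (tissue-specific, stage-trending and
#' unexpressed fractions), mirroring the biological claim that X:AA
#' dynamics arise from gene content rather than compensation itself.
#'
#' @param n_autosomal_genes,n_x_genes Gene counts per chromosome class.
#' @param n_tissues Number of tissues (named from `tissue_names`).
#' @param n_stages Number of developmental stages per tissue (ranks 1..n,
#'   young to old), one sample per tissue x stage.
#' @param compensation_factor X-linked expression multiplier in [0.5, 1.5];
#'   1 = full dosage compensation, 0.5 = none.
#' @param frac_tissue_specific_x,frac_tissue_specific_a Proportion of each
#'   class expressed in a single assigned tissue and near-zero elsewhere.
#' @param frac_stage_pos_x,frac_stage_neg_x,frac_stage_pos_a,frac_stage_neg_a
#'   Proportions of monotone stage-trending genes per class.
#' @param frac_unexpressed_x,frac_unexpressed_a Proportions forced to 0 in
#'   every sample (decayed genes).
#' @param log_sd Log-scale per-gene baseline dispersion (sdlog).
#' @param baseline_log_mean Log-scale baseline mean (meanlog); the default
#'   `log(20)` puts almost all expressed genes above FPKM = 1 so that the
#'   FPKM > 1 filter truncates negligibly.
#' @param sample_log_sd Multiplicative log-normal sample noise (sdlog).
#' @param proteome_log_sd Log-normal noise of the derived proteome.
#' @param proteome_exponent Power-law exponent b in protein = mRNA^b.
#' @param stage_fold Total fold change across stages for trending genes
#'   (log-linear ramp, geometric mean 1).
#' @param off_level Relative expression of a tissue-specific gene outside
#'   its assigned tissue (near-zero, but > 0).
#' @param tissue_weights_x,tissue_weights_a Optional assignment
#'   probabilities of specific genes over tissues (uniform when `NULL`).
#' @param outgroup_scale Global between-species expression scale factor s.
#' @param outgroup_x_chroms Outgroup autosomes carrying orthologs of focal
#'   X genes (chicken-like chr1/chr4 by default).
#' @param chrom_length Simulated chromosome length (bp) for TSS placement.
#' @param palette_size_x,palette_size_a Per-gene chromatin state palette
#'   sizes (out of the 15-state vocabulary; 15_Quies always included).
#' @param quies_frac_x,quies_frac_a Expected fraction of promoter bases in
#'   the quiescent state per class.
#' @param tile_width Chromatin tile width (bp) inside promoters.
#' @param tissue_names Tissue labels recycled/truncated to `n_tissues`.
#' @param seed Integer seed; all generators derive from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_autosomal_genes = 2000L, n_x_genes = 200L,
                       n_tissues = 5L, n_stages = 10L,
                       compensation_factor = 1.0,
                       frac_tissue_specific_x = 0, frac_tissue_specific_a = 0,
                       frac_stage_pos_x = 0, frac_stage_neg_x = 0,
                       frac_stage_pos_a = 0, frac_stage_neg_a = 0,
                       frac_unexpressed_x = 0, frac_unexpressed_a = 0,
                       log_sd = 1.0, baseline_log_mean = log(20),
                       sample_log_sd = 0.1,
                       proteome_log_sd = 0.5, proteome_exponent = 1,
                       stage_fold = 8, off_level = 0.01,
                       tissue_weights_x = NULL, tissue_weights_a = NULL,
                       outgroup_scale = 1,
                       outgroup_x_chroms = c("1", "4"),
                       chrom_length = 1e7,
                       palette_size_x = 12L, palette_size_a = 9L,
                       quies_frac_x = 0.5, quies_frac_a = 0.3,
                       tile_width = 200L,
                       tissue_names = c("brain", "cerebellum", "heart",
                                        "liver", "testis", "kidney", "ovary"),
                       seed = 1L) {
  p <- as.list(environment())
  props <- c(frac_tissue_specific_x, frac_tissue_specific_a,
             frac_stage_pos_x, frac_stage_neg_x, frac_stage_pos_a,
             frac_stage_neg_a, frac_unexpressed_x, frac_unexpressed_a)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (frac_unexpressed_x + frac_tissue_specific_x + frac_stage_pos_x +
        frac_stage_neg_x > 1)
    stop("X-gene role fractions must sum to at most 1")
  if (frac_unexpressed_a + frac_tissue_specific_a + frac_stage_pos_a +
        frac_stage_neg_a > 1)
    stop("autosomal role fractions must sum to at most 1")
  if (compensation_factor < 0.5 || compensation_factor > 1.5)
    stop("compensation_factor must lie in [0.5, 1.5]")
  stopifnot(log_sd > 0, proteome_log_sd > 0, sample_log_sd >= 0,
            n_autosomal_genes >= 0, n_x_genes >= 0, n_tissues >= 1,
            n_stages >= 1)
  p$tissue_names <- rep_len(tissue_names, n_tissues)
  class(p) <- "sim_params"
  p
}

#' Canned parameters: divergent gene content under full compensation
#'
#' The study condition behind the central qualitative claim: with
#' `compensation_factor = 1` but X-enriched tissue-specific genes (all
#' assigned to testis), X-enriched stage-trending genes and excess
#' unexpressed X genes, tissue-wise X:AA ratios diverge widely while the
#' ortholog-based X:XX ratio stays flat at 1 in every tissue.
#'
#' @param seed Integer seed.
#' @return A `sim_params` object.
#' @export
sim_params_divergence <- function(seed = 1L) {
  sim_params(n_autosomal_genes = 4000L, n_x_genes = 400L,
             n_tissues = 5L, n_stages = 10L,
             compensation_factor = 1.0,
             frac_tissue_specific_x = 0.5, frac_tissue_specific_a = 0.3,
             tissue_weights_x = c(0, 0, 0, 0, 1),  # all X-specific -> testis
             frac_stage_pos_x = 0.15, frac_stage_neg_x = 0.02,
             frac_stage_pos_a = 0.05, frac_stage_neg_a = 0.05,
             frac_unexpressed_x = 0.15, frac_unexpressed_a = 0.05,
             seed = seed)
}

#' Simulate a gene annotation
#'
#' Autosomal genes are assigned round-robin to chromosomes "1".."22", X
#' genes to "X"; TSS uniform on `[0, chrom_length)`; strand Bernoulli(1/2).
#'
#' @param params A [sim_params()].
#' @return A [gene_annotation()].
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n_a <- params$n_autosomal_genes
  n_x <- params$n_x_genes
  with_seed(derive_seed(params$seed, "genome"), {
    ids <- c(sprintf("AG%05d", seq_len(n_a)), sprintf("XG%05d", seq_len(n_x)))
    chrom <- c(as.character(rep_len(1:22, n_a)), rep("X", n_x))
    gene_annotation(
      gene_id = ids, chromosome = chrom, biotype = "protein_coding",
      tss = as.integer(floor(stats::runif(n_a + n_x, 0,
                                          params$chrom_length - 3001))),
      strand = sample(c("+", "-"), n_a + n_x, replace = TRUE)
    )
  })
}

# Assign structural roles (background / unexpressed / tissue_specific /
# stage_pos / stage_neg) within one chromosome class, deterministically
# under the derived seed already set by the caller.
assign_roles <- function(ids, fr_unexpr, fr_spec, fr_pos, fr_neg) {
  n <- length(ids)
  roles <- rep("background", n)
  counts <- c(unexpressed = round(fr_unexpr * n),
              tissue_specific = round(fr_spec * n),
              stage_pos = round(fr_pos * n),
              stage_neg = round(fr_neg * n))
  pool <- sample(seq_len(n))
  at <- 0L
  for (r in names(counts)) {
    k <- counts[[r]]
    if (k > 0L) roles[pool[at + seq_len(k)]] <- r
    at <- at + k
  }
  data.frame(gene_id = ids, role = roles, stringsAsFactors = FALSE)
}

#' Simulate a developmental expression matrix
#'
#' Per-gene baselines are log-normal(`baseline_log_mean`, `log_sd`). The
#' noise-free expected value of gene g in sample s is
#' baseline x tissue factor x stage factor ("ancestral" level); every
#' X-linked gene is additionally multiplied by `compensation_factor`, and
#' observed values carry multiplicative log-normal sample noise.
#' Tissue-specific genes sit at baseline in their one assigned tissue and
#' at `off_level` x baseline elsewhere; stage-trending genes follow a
#' log-linear ramp over stage rank spanning `stage_fold` with geometric
#' mean 1 (increasing for positive, decreasing for negative trends);
#' unexpressed genes are 0 everywhere.
#'
#' The returned matrix carries a `$truth` component with the role table,
#' the ancestral (pre-compensation, noise-free) expectation matrix, and the
#' parameters — consumed by [simulate_outgroup()] and by recovery tests.
#'
#' @param annotation Output of [simulate_genome()].
#' @param params A [sim_params()].
#' @return An [expr_matrix()] with an extra `truth` component.
#' @export
simulate_expression <- function(annotation, params) {
  stopifnot(inherits(params, "sim_params"))
  tissues <- params$tissue_names
  stages <- seq_len(params$n_stages)
  samples <- expand.grid(stage_rank = stages, tissue = tissues,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$tissue, sprintf("s%02d", samples$stage_rank),
                      sep = "."),
    species = "focal", tissue = samples$tissue,
    stage_label = sprintf("s%02d", samples$stage_rank),
    stage_rank = samples$stage_rank, sex = "unknown",
    stringsAsFactors = FALSE
  )
  n_genes <- nrow(annotation)
  xg <- is_x_gene(annotation)
  with_seed(derive_seed(params$seed, "expression"), {
    baseline <- stats::rlnorm(n_genes, params$baseline_log_mean, params$log_sd)
    roles <- rbind(
      assign_roles(annotation$gene_id[!xg], params$frac_unexpressed_a,
                   params$frac_tissue_specific_a, params$frac_stage_pos_a,
                   params$frac_stage_neg_a),
      assign_roles(annotation$gene_id[xg], params$frac_unexpressed_x,
                   params$frac_tissue_specific_x, params$frac_stage_pos_x,
                   params$frac_stage_neg_x)
    )
    roles <- roles[match(annotation$gene_id, roles$gene_id), , drop = FALSE]
    roles$assigned_tissue <- NA_character_
    spec <- roles$role == "tissue_specific"
    if (any(spec)) {
      w_a <- params$tissue_weights_a %||% rep(1, length(tissues))
      w_x <- params$tissue_weights_x %||% rep(1, length(tissues))
      pick <- character(sum(spec))
      pick[xg[spec]] <- sample(tissues, sum(spec & xg), replace = TRUE,
                               prob = w_x / sum(w_x))
      pick[!xg[spec]] <- sample(tissues, sum(spec & !xg), replace = TRUE,
                                prob = w_a / sum(w_a))
      roles$assigned_tissue[spec] <- pick
    }
    # ancestral expectation mu[g, s]
    mu <- matrix(baseline, n_genes, nrow(samples),
                 dimnames = list(annotation$gene_id, samples$sample_id))
    if (any(spec)) {
      off <- outer(roles$assigned_tissue[spec], samples$tissue, `!=`)
      mu[spec, ][off] <- mu[spec, ][off] * params$off_level
    }
    if (params$n_stages > 1L) {
      ramp <- exp(log(params$stage_fold) *
                    ((samples$stage_rank - 1) / (params$n_stages - 1) - 0.5))
      pos <- roles$role == "stage_pos"
      neg <- roles$role == "stage_neg"
      if (any(pos)) mu[pos, ] <- sweep(mu[pos, , drop = FALSE], 2L, ramp, `*`)
      if (any(neg)) mu[neg, ] <- sweep(mu[neg, , drop = FALSE], 2L,
                                       1 / ramp, `*`)
    }
    mu[roles$role == "unexpressed", ] <- 0
    E <- mu * ifelse(xg, params$compensation_factor, 1)
    if (params$sample_log_sd > 0)
      E <- E * matrix(stats::rlnorm(length(E), 0, params$sample_log_sd),
                      nrow(E), ncol(E))
    x <- expr_matrix(E, annotation, samples)
    x$truth <- list(roles = roles, ancestral = mu,
                    compensation_factor = params$compensation_factor,
                    params = params)
    x
  })
}

#' Simulate an outgroup species with 1:1 orthologs
#'
#' Every focal gene receives one outgroup ortholog. Orthologs of focal
#' X-linked genes are placed on the outgroup autosomes named in
#' `params$outgroup_x_chroms` (round-robin; emulating chicken chr1/chr4),
#' all other orthologs inherit the focal chromosome label. Outgroup
#' expression equals the focal ancestral (pre-compensation) expectation
#' times the global species scale `outgroup_scale` times log-normal sample
#' noise, so that after median scaling and AA:AA normalization the
#' ground-truth X:XX ratio equals `compensation_factor` and AA:AA equals 1.
#'
#' @param focal An [expr_matrix()] produced by [simulate_expression()]
#'   (carries the ancestral truth component).
#' @param params The same [sim_params()].
#' @return A list with elements `map` ([ortholog_map()]), `expression`
#'   (outgroup [expr_matrix()]) and `annotation`.
#' @export
simulate_outgroup <- function(focal, params) {
  stopifnot(inherits(focal, "expr_matrix"), !is.null(focal$truth))
  ann <- focal$genes
  xg <- is_x_gene(ann)
  out_ids <- paste0("og_", ann$gene_id)
  out_chrom <- ann$chromosome
  out_chrom[xg] <- rep_len(params$outgroup_x_chroms, sum(xg))
  with_seed(derive_seed(params$seed, "outgroup"), {
    out_ann <- gene_annotation(
      gene_id = out_ids, chromosome = out_chrom, biotype = "protein_coding",
      tss = as.integer(floor(stats::runif(length(out_ids), 0,
                                          params$chrom_length - 3001))),
      strand = sample(c("+", "-"), length(out_ids), replace = TRUE)
    )
    mu <- focal$truth$ancestral
    E <- mu * params$outgroup_scale
    if (params$sample_log_sd > 0)
      E <- E * matrix(stats::rlnorm(length(E), 0, params$sample_log_sd),
                      nrow(E), ncol(E))
    rownames(E) <- out_ids
    samples <- focal$samples
    samples$species <- "outgroup"
    out_x <- expr_matrix(E, out_ann, samples)
    map <- ortholog_map(ann$gene_id, out_ids, ann$chromosome, out_chrom)
    list(map = map, expression = out_x, annotation = out_ann)
  })
}

#' Simulate a proteome from an mRNA matrix
#'
#' Protein abundance = mRNA^b x log-normal noise (iBAQ-like units); zero
#' mRNA gives zero protein.
#'
#' @param x An mRNA [expr_matrix()].
#' @param params A [sim_params()] (`proteome_exponent`, `proteome_log_sd`).
#' @return An [expr_matrix()] of protein abundances.
#' @export
simulate_proteome <- function(x, params) {
  with_seed(derive_seed(params$seed, "proteome"), {
    P <- x$E ^ params$proteome_exponent
    if (params$proteome_log_sd > 0)
      P <- P * matrix(stats::rlnorm(length(P), 0, params$proteome_log_sd),
                      nrow(P), ncol(P))
    P[x$E == 0] <- 0
    expr_matrix(P, x$genes, x$samples)
  })
}

#' Simulate chromHMM-like segmentations
#'
#' Each gene receives a fixed state palette (a subset of the 15-state
#' vocabulary always containing 15_Quies) of size `palette_size_x` for
#' X-linked genes and `palette_size_a` for autosomal genes. Per epigenome,
#' each promoter (TSS -2 kb / +1 kb, strand-aware) is tiled with
#' `tile_width`-bp segments whose states are drawn from the gene's palette
#' (15_Quies with probability `quies_frac`); the remaining chromosome is
#' filled with 15_Quies. Overlapping promoters are truncated at their
#' neighbour's boundary so each epigenome is a valid non-overlapping
#' segmentation.
#'
#' @param annotation A [gene_annotation()] with TSS and strand.
#' @param params A [sim_params()].
#' @param n_epigenomes Number of epigenomes to simulate.
#' @return A list of `chrom_segmentation` objects.
#' @export
simulate_chromatin <- function(annotation, params, n_epigenomes = 10L) {
  xg <- is_x_gene(annotation)
  palettes <- with_seed(derive_seed(params$seed, "palette"), {
    lapply(seq_len(nrow(annotation)), function(i) {
      size <- if (xg[i]) params$palette_size_x else params$palette_size_a
      size <- max(1L, min(size, length(chromhmm_states)))
      if (size == 1L) "15_Quies"
      else c("15_Quies",
             sample(setdiff(chromhmm_states, "15_Quies"), size - 1L))
    })
  })
  proms <- promoter_intervals(annotation)
  proms$is_x <- xg[match(proms$gene_id, annotation$gene_id)]
  proms$palette <- palettes[match(proms$gene_id, annotation$gene_id)]
  lapply(seq_len(n_epigenomes), function(e) {
    with_seed(derive_seed(params$seed, paste0("chromatin", e)), {
      pieces <- lapply(split(proms, proms$chromosome), function(pc) {
        pc <- pc[order(pc$start), , drop = FALSE]
        cur <- 0L
        rows <- vector("list", 2L * nrow(pc) + 1L)
        k <- 0L
        for (i in seq_len(nrow(pc))) {
          s <- max(pc$start[i], cur)
          en <- pc$end[i]
          if (s >= en) next
          if (s > cur) {
            k <- k + 1L
            rows[[k]] <- data.frame(chrom = pc$chromosome[i], start = cur,
                                    end = s, state = "15_Quies",
                                    stringsAsFactors = FALSE)
          }
          qf <- if (pc$is_x[i]) params$quies_frac_x else params$quies_frac_a
          pal <- pc$palette[[i]]
          bounds <- unique(c(seq(s, en, by = params$tile_width), en))
          nt <- length(bounds) - 1L
          st <- if (length(pal) == 1L) rep(pal, nt) else
            ifelse(stats::runif(nt) < qf, "15_Quies",
                   sample(setdiff(pal, "15_Quies"), nt, replace = TRUE))
          k <- k + 1L
          rows[[k]] <- data.frame(chrom = pc$chromosome[i],
                                  start = bounds[-length(bounds)],
                                  end = bounds[-1L], state = st,
                                  stringsAsFactors = FALSE)
          cur <- en
        }
        if (cur < params$chrom_length) {
          k <- k + 1L
          rows[[k]] <- data.frame(chrom = pc$chromosome[1L], start = cur,
                                  end = as.integer(params$chrom_length),
                                  state = "15_Quies", stringsAsFactors = FALSE)
        }
        do.call(rbind, rows[seq_len(k)])
      })
      chrom_segmentation(sprintf("E%03d", e), do.call(rbind, pieces))
    })
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the exact TSV/BED dialects the loaders consume, so the pipeline
#' can be run end-to-end from generated files.
#'
#' @param dir Output directory (created if needed).
#' @param params A [sim_params()].
#' @param n_epigenomes Number of chromatin epigenomes to write.
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_dataset <- function(dir, params, n_epigenomes = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_genome(params)
  x <- simulate_expression(ann, params)
  og <- simulate_outgroup(x, params)
  prot <- simulate_proteome(x, params)
  segs <- simulate_chromatin(ann, params, n_epigenomes)
  paths <- list(
    annotation = file.path(dir, "genes.tsv"),
    samples = file.path(dir, "samples.tsv"),
    expression = file.path(dir, "expression.tsv"),
    outgroup_annotation = file.path(dir, "outgroup_genes.tsv"),
    outgroup_samples = file.path(dir, "outgroup_samples.tsv"),
    outgroup_expression = file.path(dir, "outgroup_expression.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    proteome = file.path(dir, "proteome.tsv"),
    segmentation_dir = file.path(dir, "chromatin")
  )
  write_gene_annotation(ann, paths$annotation)
  write_sample_sheet(x$samples, paths$samples)
  write_expression_matrix(x, paths$expression)
  write_gene_annotation(og$annotation, paths$outgroup_annotation)
  write_sample_sheet(og$expression$samples, paths$outgroup_samples)
  write_expression_matrix(og$expression, paths$outgroup_expression)
  write_ortholog_map(og$map, paths$orthologs)
  write_expression_matrix(prot, paths$proteome)
  dir.create(paths$segmentation_dir, showWarnings = FALSE)
  for (s in segs)
    write_segmentation(s, file.path(paths$segmentation_dir,
                                    paste0(s$epigenome_id, ".bed")))
  invisible(paths)
}
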