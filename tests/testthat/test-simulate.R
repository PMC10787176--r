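# Generator determinism, parameter validation, and ground-truth structure.

test_that("generators are fully deterministic under a fixed seed", {
  p <- sim_params(n_autosomal_genes = 100L, n_x_genes = 20L,
                  n_tissues = 2L, n_stages = 4L,
                  frac_tissue_specific_x = 0.2, frac_stage_pos_a = 0.1,
                  seed = 42L)
  a1 <- simulate_genome(p); a2 <- simulate_genome(p)
  expect_identical(a1, a2)
  x1 <- simulate_expression(a1, p); x2 <- simulate_expression(a1, p)
  expect_identical(x1$E, x2$E)
  o1 <- simulate_outgroup(x1, p); o2 <- simulate_outgroup(x1, p)
  expect_identical(o1$expression$E, o2$expression$E)
  s1 <- simulate_chromatin(a1, p, 2L); s2 <- simulate_chromatin(a1, p, 2L)
  expect_identical(s1, s2)
})

test_that("simulated genome places the requested genes per chromosome class", {
  p <- sim_params(n_autosomal_genes = 90L, n_x_genes = 10L, seed = 2L)
  ann <- simulate_genome(p)
  expect_equal(sum(ann$chromosome == "X"), 10L)
  expect_equal(sum(ann$chromosome != "X"), 90L)
  expect_true(all(ann$tss >= 0))

  p0 <- sim_params(n_autosomal_genes = 50L, n_x_genes = 0L, seed = 2L)
  ann0 <- simulate_genome(p0)
  x0 <- simulate_expression(ann0, p0)
  expect_equal(sum(ann0$chromosome == "X"), 0L)
  expect_error(xaa_ratio(x0, cutoff = 0), "no X-linked genes")
})

test_that("parameter validation rejects impossible study conditions", {
  expect_error(sim_params(frac_unexpressed_x = 1.2), "proportions")
  expect_error(sim_params(frac_unexpressed_x = 0.6,
                          frac_tissue_specific_x = 0.5), "sum")
  expect_error(sim_params(compensation_factor = 2), "compensation_factor")
})

test_that("unexpressed fractions and role structure appear in the matrix", {
  sim <- quick_sim(seed = 9, frac_unexpressed_x = 0.3,
                   frac_unexpressed_a = 0.1)
  xg <- sim$ann$chromosome == "X"
  zero_rows <- rowSums(sim$x$E) == 0
  expect_equal(mean(zero_rows[xg]), 0.3, tolerance = 0.05)
  expect_equal(mean(zero_rows[!xg]), 0.1, tolerance = 0.05)
  # generated matrices satisfy the container invariants
  expect_true(all(sim$x$E >= 0))
  expect_true(all(rownames(sim$x$E) %in% sim$ann$gene_id))
})

test_that("tissue-specific genes are confined to their assigned tissue", {
  sim <- quick_sim(seed = 10, frac_tissue_specific_x = 0.3,
                   frac_tissue_specific_a = 0.2, n_tissues = 3L)
  roles <- sim$x$truth$roles
  spec <- roles[roles$role == "tissue_specific", ]
  expect_true(all(spec$assigned_tissue %in% sim$x$samples$tissue))
  for (i in utils::head(seq_len(nrow(spec)), 20L)) {
    on <- select_samples(sim$x, tissue = spec$assigned_tissue[i])
    off <- setdiff(colnames(sim$x$E), on)
    expect_gt(mean(sim$x$E[spec$gene_id[i], on]),
              10 * mean(sim$x$E[spec$gene_id[i], off]))
  }
})

test_that("zero-noise outgroup with unit scale reproduces the compensation factor exactly", {
  sim <- quick_sim(seed = 3, cf = 0.75, sample_log_sd = 0)
  og <- simulate_outgroup(sim$x, sim$params)
  r <- xxx_pipeline(og$map, sim$x, og$expression, cutoff = 1)
  expect_equal(r$x_xx, 0.75, tolerance = 1e-12)
  expect_equal(r$aa_aa, 1, tolerance = 1e-12)
})

test_that("proteome derivation is exact at zero noise and compresses range for b < 1", {
  sim <- quick_sim(seed = 4)
  p0 <- sim$params; p0$proteome_log_sd <- 1e-12; p0$proteome_exponent <- 1
  prot <- simulate_proteome(sim$x, p0)
  expect_equal(prot$E, sim$x$E, tolerance = 1e-9)

  p5 <- sim$params; p5$proteome_log_sd <- 1e-12; p5$proteome_exponent <- 0.5
  prot5 <- simulate_proteome(sim$x, p5)
  pos <- sim$x$E > 0
  expect_equal(max(prot5$E[pos]) / min(prot5$E[pos]),
               sqrt(max(sim$x$E[pos]) / min(sim$x$E[pos])),
               tolerance = 1e-6)
})

test_that("single-state palettes give exactly one state per gene", {
  p <- sim_params(n_autosomal_genes = 20L, n_x_genes = 5L,
                  palette_size_x = 1L, palette_size_a = 1L, seed = 8L)
  ann <- simulate_genome(p)
  segs <- simulate_chromatin(ann, p, 1L)
  prof <- state_profiles(promoter_intervals(ann), segs)
  d <- state_diversity(prof, ann)
  expect_true(all(d$per_gene$n_states == 1L))
})

test_that("a written synthetic dataset reloads into an identical pipeline input", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_autosomal_genes = 60L, n_x_genes = 12L,
                  n_tissues = 2L, n_stages = 3L, seed = 5L)
  paths <- write_synthetic_dataset(dir, p, n_epigenomes = 1L)
  ann <- read_gene_annotation(paths$annotation)
  x <- suppressMessages(read_expression_matrix(paths$expression, ann,
                                               paths$samples))
  ref <- simulate_expression(simulate_genome(p), p)
  expect_identical(x$E, ref$E)
  seg <- read_segmentation(list.files(paths$segmentation_dir,
                                      full.names = TRUE)[1L])
  expect_gt(nrow(seg$intervals), 0L)
})
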