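# Tau specificity, max-tissue assignment, tissue-specific gene sets.

test_that("tau matches direct evaluation and its boundary cases", {
  expect_equal(tau(c(1, 0, 0, 0)), 1.0)
  expect_equal(tau(c(5, 5, 5, 5)), 0.0)
  expect_equal(tau(c(8, 4, 2, 2)), (0 + 0.5 + 0.75 + 0.75) / 3)
  expect_error(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(5), "two contexts")
  expect_error(tau(c(-1, 2)), "non-negative")
})

test_that("tau is scale-invariant and monotone under concentration", {
  set.seed(71)
  for (i in 1:50) {
    v <- stats::runif(sample(3:8, 1L), 0, 50)
    if (max(v) == 0) next
    expect_equal(tau(v * stats::runif(1, 0.1, 10)), tau(v),
                 tolerance = 1e-12)
    # move mass from a non-max tissue to the max tissue
    w <- v
    i_max <- which.max(w)
    i_min <- which(w < max(w))[1L]
    if (!is.na(i_min)) {
      shift <- w[i_min] * 0.5
      w[i_max] <- w[i_max] + shift
      w[i_min] <- w[i_min] - shift
      expect_gte(tau(w) + 1e-12, tau(v))
    }
  }
})

test_that("tissue means average a tissue's stages; stage tau works within tissues", {
  x <- make_xmat(rbind(c(2, 4, 10, 10), c(1, 1, 1, 1)),
                 c("X", "1"),
                 sample_tissues = c("brain", "brain", "liver", "liver"),
                 stage_ranks = c(1, 2, 1, 2))
  tm <- tissue_mean_expression(x)
  expect_equal(tm["g01", "brain"], 3)
  expect_equal(tm["g01", "liver"], 10)

  st <- stage_specificity(x, "brain")
  expect_equal(st$tau_stage[st$gene_id == "g02"], 0)
  expect_error(stage_specificity(x, "nowhere"), "no samples")

  one_stage <- make_xmat(c(1, 2), c("X", "1"))
  expect_error(stage_specificity(one_stage, "brain"), "two stages")
})

test_that("stage-trending genes score higher stage tau than flat genes", {
  sim <- quick_sim(seed = 72, n_tissues = 1L, n_stages = 8L,
                   frac_stage_pos_a = 0.3)
  st <- stage_specificity(sim$x, sim$x$samples$tissue[1L])
  roles <- sim$x$truth$roles
  trending <- st$tau_stage[st$gene_id %in%
                             roles$gene_id[roles$role == "stage_pos"]]
  flat <- st$tau_stage[st$gene_id %in%
                         roles$gene_id[roles$role == "background"]]
  expect_gt(stats::median(trending), stats::median(flat))
})

test_that("max-tissue assignment breaks ties deterministically and flags them", {
  tbl <- rbind(g1 = c(brain = 9, liver = 1),
               g2 = c(brain = 2, liver = 2),
               g3 = c(brain = 0, liver = 0))
  mt <- max_tissue_assignment(tbl)
  expect_equal(mt$max_tissue[mt$gene_id == "g1"], "brain")
  expect_equal(mt$max_tissue[mt$gene_id == "g2"], "brain")  # sorted first
  expect_true(mt$tie[mt$gene_id == "g2"])
  expect_false("g3" %in% mt$gene_id)                        # all-zero
})

test_that("the simulated testis preference of X genes is recovered", {
  p <- sim_params(n_autosomal_genes = 1000L, n_x_genes = 300L,
                  n_tissues = 5L, n_stages = 4L,
                  frac_tissue_specific_x = 0.34,
                  tissue_weights_x = c(0, 0, 0, 0, 1),  # testis
                  frac_tissue_specific_a = 0.1, seed = 73L)
  ann <- simulate_genome(p)
  x <- simulate_expression(ann, p)
  mt <- max_tissue_assignment(tissue_mean_expression(x))
  is_x <- ann$chromosome[match(mt$gene_id, ann$gene_id)] == "X"
  frac_testis <- mean(mt$max_tissue[is_x] == "testis")
  # 34% are testis-specific by construction; background genes add a ~1/5
  # share of ties-of-noise, so the recovered fraction sits near 0.34 + 0.66/5
  expect_lt(abs(frac_testis - (0.34 + 0.66 / 5)), 0.09)
  fe <- tissue_enrichment_test(mt, ann, "testis")
  expect_lt(fe$p, 1e-6)
  expect_gt(fe$odds_ratio, 1)
})

test_that("tissue-specific gene sets recover the generator labels", {
  p <- sim_params(n_autosomal_genes = 600L, n_x_genes = 100L,
                  n_tissues = 4L, n_stages = 3L,
                  frac_tissue_specific_x = 0.3,
                  frac_tissue_specific_a = 0.2, seed = 74L)
  ann <- simulate_genome(p)
  x <- simulate_expression(ann, p)
  ts <- suppressMessages(tissue_specific_genes(x, tau_threshold = 0.8))
  truth <- x$truth$roles
  true_spec <- truth$gene_id[truth$role == "tissue_specific"]
  called_spec <- ts$genes$gene_id[ts$genes$specific]
  recall <- mean(true_spec %in% called_spec)
  expect_gte(recall, 0.95)
  # assigned tissues match the generator assignment
  g <- ts$genes[ts$genes$gene_id %in% true_spec & ts$genes$specific, ]
  expect_gt(mean(g$max_tissue ==
                   truth$assigned_tissue[match(g$gene_id, truth$gene_id)]),
            0.95)
})

test_that("ratio-vs-fraction correlation handles exact and degenerate orderings", {
  r <- c(a = 0.2, b = 0.5, c = 0.9, d = 1.2)
  expect_equal(ratio_vs_specific_fraction(r, r)$rho, 1)
  expect_equal(ratio_vs_specific_fraction(r, -r)$rho, -1)
  expect_error(ratio_vs_specific_fraction(r[1:2], r[1:2]), "3 common")
})
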