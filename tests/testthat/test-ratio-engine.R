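# X:AA point ratio, bootstrap, cutoff series, HKG references,
# unexpressed fractions and multi-source combination.

test_that("point ratio is the ratio of filtered class means", {
  x <- make_xmat(c(2, 2, 1, 3), c("X", "X", "1", "2"))
  expect_equal(xaa_ratio(x, cutoff = 0)$ratio, 1.0)

  x2 <- make_xmat(c(4, 1, 3), c("X", "1", "2"))
  expect_equal(xaa_ratio(x2, cutoff = 0)$ratio, 2.0)

  # filter-then-mean: X {0.5, 4} at cutoff 1 keeps only 4
  x3 <- make_xmat(c(0.5, 4, 2, 2), c("X", "X", "1", "2"))
  est <- xaa_ratio(x3, cutoff = 1)
  expect_equal(est$ratio, 2.0)
  expect_equal(est$n_x, 1L)
  expect_equal(est$n_a, 2L)

  # ratio of means, not mean of ratios: skewed values distinguish them
  x4 <- make_xmat(c(10, 1, 1, 100), c("X", "X", "1", "2"))
  expect_equal(xaa_ratio(x4, cutoff = 0)$ratio, 5.5 / 50.5)
})

test_that("ratios are invariant to a global rescaling of the matrix", {
  sim <- quick_sim(seed = 21)
  k <- 7.3
  xk <- expr_matrix(sim$x$E * k, sim$x$genes, sim$x$samples)
  expect_equal(xaa_ratio(xk, tissue = "brain", cutoff = 0)$ratio,
               xaa_ratio(sim$x, tissue = "brain", cutoff = 0)$ratio,
               tolerance = 1e-12)
  u <- unexpressed_fraction(sim$x, cutoff = 0)
  uk <- unexpressed_fraction(xk, cutoff = 0)
  expect_equal(u$fraction, uk$fraction)
})

test_that("bootstrap CI is deterministic, degenerate-safe and nested across levels", {
  # degenerate: all autosomal genes share one value -> zero-width CI
  x <- make_xmat(c(3, 2, 2, 2, 2), c("X", "1", "2", "3", "4"))
  b <- bootstrap_xaa(x, cutoff = 0, n_boot = 50, seed = 1)
  expect_equal(b$ci_low, 1.5)
  expect_equal(b$ci_high, 1.5)

  sim <- quick_sim(seed = 22)
  b1 <- bootstrap_xaa(sim$x, tissue = "brain", n_boot = 300, seed = 9)
  b2 <- bootstrap_xaa(sim$x, tissue = "brain", n_boot = 300, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)

  b90 <- bootstrap_xaa(sim$x, tissue = "brain", n_boot = 300, seed = 9,
                       level = 0.90)
  b99 <- bootstrap_xaa(sim$x, tissue = "brain", n_boot = 300, seed = 9,
                       level = 0.99)
  expect_lte(b99$ci_low, b90$ci_low)
  expect_gte(b99$ci_high, b90$ci_high)

  # cannot subsample more autosomal genes than exist
  small <- make_xmat(c(3, 3, 2), c("X", "X", "1"))
  expect_error(bootstrap_xaa(small, cutoff = 0), "without replacement")
})

test_that("bootstrap CI width shrinks stochastically as the autosome pool grows", {
  widths <- vapply(c(300L, 3000L), function(n_a) {
    sim <- quick_sim(seed = 30, n_a = n_a, n_x = 50L)
    b <- bootstrap_xaa(sim$x, n_boot = 400, seed = 5)
    b$ci_high - b$ci_low
  }, numeric(1L))
  expect_lt(widths[2L], widths[1L])
})

test_that("cutoff series applies the zero-cutoff and all-genes conventions", {
  # X at 0.5, A at 2: cutoff 0 -> 0.25; cutoff 1 empties X -> missing
  x <- make_xmat(c(0.5, 0.5, 2, 2), c("X", "X", "1", "2"))
  res <- ratio_cutoff_series(x, cutoffs = c(0, 1))
  expect_equal(res$ratio[res$cutoff_label == "0"], 0.25)
  expect_true(is.na(res$ratio[res$cutoff_label == "1"]))
  expect_equal(res$ratio[res$cutoff_label == "all"], 0.25)

  # sentinel differs from cutoff 0 exactly when a value is 0
  x0 <- make_xmat(c(0, 4, 2, 2), c("X", "X", "1", "2"))
  res0 <- ratio_cutoff_series(x0, cutoffs = 0)
  expect_equal(res0$ratio[res0$cutoff_label == "all"], 1.0)   # (0+4)/2 / 2
  expect_equal(res0$ratio[res0$cutoff_label == "0"], 2.0)     # 4 / 2

  # no sub-threshold values -> all entries identical
  xc <- make_xmat(c(5, 6, 7, 8), c("X", "1", "2", "3"))
  resc <- ratio_cutoff_series(xc, cutoffs = c(0, 0.5, 1))
  expect_equal(length(unique(resc$ratio)), 1L)
})

test_that("housekeeping-gene ratios use the stated reference sets", {
  x <- make_xmat(c(5, 5, 5, 9, 2), c("X", "X", "3", "4", "5"),
                 gene_ids = c("x1", "xh", "ah1", "a2", "ah2"))
  r <- hkg_ratios(x, ahkg_ids = c("ah1", "ah2"), xhkg_ids = "xh",
                  cutoff = 0)
  expect_equal(r$xhkg_to_ahkg, 5 / 3.5)
  expect_equal(r$x_to_ahkg, 5 / 3.5)
  expect_error(hkg_ratios(x, ahkg_ids = "nope", xhkg_ids = "xh",
                          cutoff = 0), "AHKG")
})

test_that("stage series: X:AHKG tracks rising X-specific expression while XHKG:AHKG stays flat", {
  sim <- quick_sim(seed = 31, n_a = 600L, n_x = 120L, n_tissues = 1L,
                   n_stages = 8L, frac_stage_pos_x = 0.4)
  roles <- sim$x$truth$roles
  xg <- sim$ann$chromosome == "X"
  ahkg <- roles$gene_id[roles$role == "background" & !xg]
  xhkg <- roles$gene_id[roles$role == "background" & xg]
  stages <- sort(unique(sim$x$samples$stage_rank))
  rr <- t(vapply(stages, function(st) {
    ids <- select_samples(sim$x, stage_rank = st)
    unlist(hkg_ratios(sim$x, ahkg, xhkg, samples = ids,
                      cutoff = 1)[c("x_to_ahkg", "xhkg_to_ahkg")])
  }, numeric(2L)))
  expect_gt(cor(rr[, 1L], stages, method = "spearman"), 0.8)
  expect_lt(abs(rr[nrow(rr), 2L] - rr[1L, 2L]) / rr[1L, 2L], 0.25)
})

test_that("unexpressed fractions and the X/A fold follow the generator truth", {
  x <- make_xmat(c(0, 2, 0, 0, 2, 2), c("X", "X", "1", "2", "3", "4"))
  u <- unexpressed_fraction(x, cutoff = 0)
  expect_equal(u$fraction, c(0.5, 0.5))
  expect_equal(unique(u$fold_x_over_a), 1.0)

  all_on <- make_xmat(c(2, 2, 2), c("X", "1", "2"))
  u2 <- unexpressed_fraction(all_on, cutoff = 0)
  expect_equal(u2$fraction, c(0, 0))
  expect_true(is.na(unique(u2$fold_x_over_a)))

  # the excess-unexpressed-X condition: fractions 0.34 vs 0.2 -> fold ~1.7
  sim <- quick_sim(seed = 32, n_a = 2000L, n_x = 400L,
                   frac_unexpressed_x = 0.34, frac_unexpressed_a = 0.2)
  u3 <- unexpressed_fraction(sim$x, cutoff = 0)
  expect_equal(unique(u3$fold_x_over_a), 1.7, tolerance = 0.08)
})

test_that("multi-source tissue ratios combine by arithmetic mean", {
  expect_equal(unname(combine_ratio_sources(list(liver = c(0.4, 0.6)))), 0.5)
  expect_equal(unname(combine_ratio_sources(list(brain = 1.3))), 1.3)
  expect_equal(unname(combine_ratio_sources(list(t = c(1, 1, 1)))), 1)
  expect_error(combine_ratio_sources(list(liver = numeric())), "empty")
})
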