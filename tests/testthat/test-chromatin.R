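# Promoter construction, state intersection, diversity and base fractions.

test_that("promoters are strand-aware reflections of the TSS window", {
  ann <- gene_annotation(c("p", "m", "edge"), c("1", "1", "2"),
                         tss = c(10000L, 10000L, 500L),
                         strand = c("+", "-", "+"))
  pr <- promoter_intervals(ann)
  expect_equal(unlist(pr[pr$gene_id == "p", c("start", "end")]),
               c(start = 8000L, end = 11000L))
  expect_equal(unlist(pr[pr$gene_id == "m", c("start", "end")]),
               c(start = 9001L, end = 12001L))
  expect_equal(unlist(pr[pr$gene_id == "edge", c("start", "end")]),
               c(start = 0L, end = 1500L))  # clipped at the boundary
  expect_true(all(pr$end - pr$start <= 3000L))
})

test_that("state intersection follows the >= 1 bp overlap rule", {
  ann <- gene_annotation("g", "chrX", tss = 2000L, strand = "+")
  pr <- promoter_intervals(ann)          # [0, 3000)
  seg <- chrom_segmentation("E1", data.frame(
    chrom = "chrX", start = c(0L, 2999L, 3000L),
    end = c(2999L, 3000L, 5000L),
    state = c("15_Quies", "1_TssA", "7_Enh")))
  hits <- intersect_states(pr, seg)
  expect_setequal(hits$state, c("15_Quies", "1_TssA"))  # 7_Enh: 0 overlap
  expect_equal(hits$bases[hits$state == "15_Quies"], 2999L)
  expect_equal(hits$bases[hits$state == "1_TssA"], 1L)

  # a full-promoter quiescent segment covers all 3000 bases
  seg2 <- chrom_segmentation("E2", data.frame(
    chrom = "chrX", start = 0L, end = 5000L, state = "15_Quies"))
  h2 <- intersect_states(pr, seg2)
  expect_equal(h2$bases, 3000L)
})

test_that("intersect_states equals a brute-force per-base scan on small inputs", {
  set.seed(101)
  for (rep in 1:5) {
    n_genes <- 4L
    ann <- gene_annotation(sprintf("g%d", 1:n_genes), "chr1",
                           tss = sort(sample(2000:7000, n_genes)),
                           strand = sample(c("+", "-"), n_genes, TRUE))
    pr <- promoter_intervals(ann)
    # random segmentation of [0, 10000)
    cuts <- sort(sample(1:9999, 8L))
    bounds <- c(0L, cuts, 10000L)
    states <- sample(c("1_TssA", "7_Enh", "15_Quies"), 9L, TRUE)
    seg <- chrom_segmentation("Ebf", data.frame(
      chrom = "chr1", start = bounds[-10L], end = bounds[-1L],
      state = states))
    hits <- intersect_states(pr, seg)
    # per-base oracle
    base_state <- rep(NA_character_, 10000L)
    for (i in 1:9) base_state[(bounds[i] + 1L):bounds[i + 1L]] <- states[i]
    for (g in seq_len(n_genes)) {
      span <- (pr$start[g] + 1L):pr$end[g]
      expected <- table(base_state[span])
      got <- hits[hits$gene_id == pr$gene_id[g], ]
      expect_setequal(got$state, names(expected))
      expect_equal(got$bases[order(got$state)],
                   as.integer(expected[order(names(expected))]))
    }
  }
})

test_that("state diversity counts distinct states and grows with epigenomes", {
  ann <- gene_annotation(c("x1", "a1"), c("X", "1"),
                         tss = c(5000L, 5000L), strand = "+")
  pr <- promoter_intervals(ann)
  seg_a <- chrom_segmentation("E1", data.frame(
    chrom = c("X", "1"), start = 3000L, end = 6000L, state = "15_Quies"))
  seg_b <- chrom_segmentation("E2", data.frame(
    chrom = c("X", "X", "1"), start = c(3000L, 4000L, 3000L),
    end = c(4000L, 6000L, 6000L),
    state = c("1_TssA", "7_Enh", "15_Quies")))
  d1 <- state_diversity(state_profiles(pr, list(seg_a)), ann)
  expect_equal(d1$median_x, 1)
  expect_equal(d1$median_a, 1)
  expect_equal(d1$p, 1)
  d2 <- state_diversity(state_profiles(pr, list(seg_a, seg_b)), ann)
  expect_gte(d2$median_x, d1$median_x)   # monotone in epigenomes
  expect_equal(d2$median_x, 3)           # {15_Quies, 1_TssA, 7_Enh}
  # "sum" mode counts per-epigenome states: 1 + 2 for x1
  d2s <- state_diversity(state_profiles(pr, list(seg_a, seg_b)), ann,
                         mode = "sum")
  expect_equal(d2s$per_gene$n_states[d2s$per_gene$gene_id == "x1"], 3L)
})

test_that("per-chromosome state base fractions sum to one", {
  ann <- gene_annotation(c("x1", "a1"), c("X", "1"),
                         tss = c(5000L, 5000L), strand = "+")
  pr <- promoter_intervals(ann)
  seg <- chrom_segmentation("E1", data.frame(
    chrom = c("X", "X", "1"), start = c(3000L, 4500L, 3000L),
    end = c(4500L, 6000L, 6000L),
    state = c("1_TssA", "7_Enh", "15_Quies")))
  f <- state_base_fraction(state_profiles(pr, list(seg)), ann)
  expect_equal(f$fraction[f$chromosome == "X"], c(0.5, 0.5))
  expect_equal(f$fraction[f$chromosome == "1"], 1)
  sums <- tapply(f$fraction, f$chromosome, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the quiescent share of X promoters is recovered from simulation", {
  p <- sim_params(n_autosomal_genes = 60L, n_x_genes = 40L,
                  quies_frac_x = 0.5, quies_frac_a = 0.3, seed = 102L)
  ann <- simulate_genome(p)
  segs <- simulate_chromatin(ann, p, 8L)
  prof <- state_profiles(promoter_intervals(ann), segs)
  f <- state_base_fraction(prof, ann)
  expect_equal(f$fraction[f$chromosome == "X" & f$state == "15_Quies"],
               0.5, tolerance = 0.05)
})
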