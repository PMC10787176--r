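# Readers/writers and the expression-matrix container.

test_that("expression TSV round-trips bit-exactly and validates input", {
  x <- quick_sim(seed = 3)$x
  path <- withr_local_tempfile()
  write_expression_matrix(x, path)
  x2 <- suppressMessages(
    read_expression_matrix(path, x$genes, x$samples))
  expect_identical(x2$E, x$E)
  expect_identical(dim(x2), dim(x))

  # malformed cell names its coordinates
  d <- utils::read.delim(path, colClasses = "character",
                         check.names = FALSE)
  d[3, 2] <- "NA"
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(path, x$genes, x$samples),
               d$gene_id[3])

  # duplicate gene ids are rejected
  d[3, 2] <- "1"
  d$gene_id[2] <- d$gene_id[1]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_matrix(path, x$genes, x$samples),
               "duplicate")
})

test_that("genes missing from the annotation or non-coding are dropped with a log", {
  E <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "zz"), c("s1", "s2")))
  ann <- gene_annotation(c("a", "b"), c("1", "X"))
  samples <- data.frame(sample_id = c("s1", "s2"), species = "h",
                        tissue = "brain", stage_label = "st1",
                        stage_rank = 1L, sex = "unknown")
  path <- withr_local_tempfile()
  utils::write.table(data.frame(gene_id = rownames(E), E,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(x <- read_expression_matrix(path, ann, samples),
                 "absent from annotation")
  expect_identical(rownames(x$E), c("a", "b"))

  ann2 <- gene_annotation(c("a", "b", "zz"), c("1", "X", "2"),
                          biotype = c("protein_coding", "protein_coding",
                                      "lncRNA"))
  expect_message(x2 <- read_expression_matrix(path, ann2, samples),
                 "non-protein-coding")
  expect_identical(rownames(x2$E), c("a", "b"))
  x3 <- read_expression_matrix(path, ann2, samples,
                               protein_coding_only = FALSE)
  expect_identical(rownames(x3$E), c("a", "b", "zz"))
})

test_that("constructors enforce the container invariants", {
  expect_error(gene_annotation(c("a", "a"), "1"), "duplicate")
  expect_error(gene_annotation("a", "1", strand = "*"), "strand")
  E <- matrix(-1, 1, 1, dimnames = list("a", "s1"))
  ann <- gene_annotation("a", "1")
  s <- data.frame(sample_id = "s1", species = "h", tissue = "t",
                  stage_label = "x", stage_rank = 1L, sex = "unknown")
  expect_error(expr_matrix(E, ann, s), "non-negative")
  expect_error(expr_matrix(abs(E), ann, s[0, ]), "absent")
})

test_that("ortholog map loading enforces the 1:1 relationship", {
  path <- withr_local_tempfile()
  writeLines(c("focal_gene\toutgroup_gene\tfocal_chrom\toutgroup_chrom",
               "a\toa\tX\t1", "b\tob\t2\t2"), path)
  m <- read_ortholog_map(path)
  expect_s3_class(m, "ortholog_map")
  expect_equal(nrow(m), 2L)

  writeLines(c("focal_gene\toutgroup_gene\tfocal_chrom\toutgroup_chrom",
               "a\toa\tX\t1", "a\tob\t2\t2"), path)
  expect_error(read_ortholog_map(path), "not 1:1")

  writeLines("focal_gene\toutgroup_gene\tfocal_chrom\toutgroup_chrom", path)
  expect_message(empty <- read_ortholog_map(path), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("BED segmentations are stored 0-based half-open and validated", {
  path <- withr_local_tempfile()
  writeLines("chrX\t0\t200\t1_TssA", path)
  seg <- read_segmentation(path, "E001")
  expect_equal(seg$intervals$end - seg$intervals$start, 200L)
  expect_equal(seg$intervals$state, "1_TssA")

  writeLines(c("chrX\t100\t100\t1_TssA"), path)
  expect_error(read_segmentation(path), "line 1")

  writeLines(c("chr1\t0\t200\t1_TssA", "chr1\t100\t300\t7_Enh"), path)
  expect_error(read_segmentation(path), "overlapping")

  file.create(path2 <- withr_local_tempfile())
  expect_message(empty <- read_segmentation(path2), "empty")
  expect_equal(nrow(empty$intervals), 0L)
})

test_that("filter_expressed honours the strict convention, idempotence and monotonicity", {
  x <- make_xmat(c(0.5, 1.0, 2.0), c("1", "2", "X"))
  expect_identical(rownames(filter_expressed(x, 1)$E), "g03")
  expect_identical(rownames(filter_expressed(x, 0)$E),
                   c("g01", "g02", "g03"))
  expect_identical(rownames(filter_expressed(x, 1, strict = FALSE)$E),
                   c("g02", "g03"))
  expect_identical(rownames(filter_expressed(x, 0, strict = FALSE)$E),
                   c("g01", "g02", "g03"))

  y <- quick_sim(seed = 5, frac_unexpressed_x = 0.2,
                 frac_unexpressed_a = 0.1)$x
  once <- filter_expressed(y, 1)
  expect_identical(filter_expressed(once, 1)$E, once$E)       # idempotent
  for (cuts in list(c(0, 0.5), c(0.5, 2), c(1, 5))) {
    hi <- filter_expressed(y, max(cuts))
    lo <- filter_expressed(y, min(cuts))
    expect_true(all(rownames(hi$E) %in% rownames(lo$E)))      # monotone
  }
})
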