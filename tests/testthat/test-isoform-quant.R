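test_that("interval arithmetic follows the 1-based inclusive convention", {
  expect_equal(interval_length(genomic_interval("chr1", 5, 5)), 1)
  expect_equal(interval_length(genomic_interval("chr1", 10, 19)), 10)
  expect_error(genomic_interval("chr1", 10, 9), "start")
  expect_error(genomic_interval("chr1", 0, 9), "1-based")
})

test_that("overlap counting matches a brute-force oracle on random instances", {
  set.seed(123)
  for (i in 1:500) {
    target <- {
      s <- sample(1:900, 1)
      genomic_interval("chrT", s, s + sample(0:80, 1))
    }
    n <- sample(0:30, 1)
    s <- sample(1:950, n, replace = TRUE)
    reads <- data.frame(chrom = sample(c("chrT", "chrU"), n, replace = TRUE),
                        start = s, end = s + sample(0:60, n, replace = TRUE))
    mo <- sample(1:5, 1)
    expect_identical(count_overlapping_reads(reads, target, mo),
                     brute_count(reads, target, mo))
  }
})

test_that("adjacency and minimum-overlap edge cases", {
  target <- genomic_interval("chr17", 100, 150)
  # a read ending at start - 1 shares no base with the target
  expect_equal(count_overlapping_reads(
    data.frame(chrom = "chr17", start = 60, end = 99), target), 0)
  expect_equal(count_overlapping_reads(
    data.frame(chrom = "chr17", start = 60, end = 100), target), 1)
  expect_equal(count_overlapping_reads(
    data.frame(chrom = "chr17", start = 100, end = 150), target), 1)
  # min_overlap filters partial overlaps
  expect_equal(count_overlapping_reads(
    data.frame(chrom = "chr17", start = 98, end = 101), target,
    min_overlap = 3), 0)
  expect_error(count_overlapping_reads(
    data.frame(chrom = "chr17", start = 1, end = 2), target,
    min_overlap = 0), ">= 1")
})

test_that("counts are additive over disjoint read subsets", {
  set.seed(9)
  s <- sample(1:500, 40, replace = TRUE)
  reads <- data.frame(chrom = "chrT", start = s, end = s + 30)
  target <- genomic_interval("chrT", 200, 260)
  total <- count_overlapping_reads(reads, target)
  split1 <- reads[1:15, ]; split2 <- reads[16:40, ]
  expect_equal(count_overlapping_reads(split1, target) +
                 count_overlapping_reads(split2, target), total)
})

test_that("RPKM formula arithmetic and scale invariance", {
  exon4 <- cd300f_exon_model()$exon4
  expect_equal(rpkm(42, 1e6, exon4), 1000)
  expect_equal(rpkm(0, 1e6, exon4), 0)
  expect_error(rpkm(10, 0, exon4), "> 0")
  # multiplying count and library by the same factor leaves RPKM fixed
  for (k in c(2, 10, 250)) {
    expect_equal(rpkm(42 * k, 1e6 * k, exon4), rpkm(42, 1e6, exon4))
  }
})

test_that("exon usage comparison reproduces the monocytic exon-4 pattern", {
  spec <- read_sim_spec(groups = list(
    hspc = list(exon4_fraction = 0.05, n_samples = 6),
    monocytic = list(exon4_fraction = 0.5, n_samples = 6),
    nonmonocytic = list(exon4_fraction = 0.1, n_samples = 6)))
  expr <- quantify_exons(simulate_reads(spec, seed = 31))
  res <- exon_usage_compare(expr)
  expect_lt(res$exon4$test$p_value, 0.05)
  expect_gt(res$exon3$test$p_value, 0.05)
  # post hoc: HSPC-like vs monocytic-like differs on exon 4
  ph <- res$exon4$posthoc
  pair <- grepl("hspc", ph$contrast) & grepl("monocytic", ph$contrast) &
    !grepl("nonmonocytic.*hspc|hspc.*nonmonocytic", ph$contrast)
  expect_true(any(ph$p_adj[pair] < 0.05))
  # direction: monocytic mean exon-4 RPKM is the largest
  m <- res$exon4$group_means
  expect_equal(names(which.max(m)), "monocytic")
  expect_error(exon_usage_compare(expr[expr$group == "hspc", ]),
               "two groups")
})
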