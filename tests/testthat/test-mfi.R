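test_that("MFI uses the median with the midpoint convention", {
  expect_equal(mfi(data.frame(x = c(1, 2, 3)), "x"), 2)
  expect_equal(mfi(data.frame(x = c(1, 2, 3, 4)), "x"), 2.5)
  expect_error(mfi(data.frame(x = numeric(0)), "x"), "empty")
  expect_error(mfi(data.frame(x = 1), "y"), "unknown channel")
  # geometric-mean option
  expect_equal(mfi(data.frame(x = c(1, 4)), "x", type = "geom_mean"), 2)
})

test_that("MFI is permutation invariant, scale equivariant and consistent", {
  x <- rlnorm(101, 3, 1)
  df <- data.frame(ch = x)
  expect_equal(mfi(df, "ch"), mfi(data.frame(ch = rev(x)), "ch"))
  expect_equal(mfi(data.frame(ch = 2.5 * x), "ch"), 2.5 * mfi(df, "ch"))
  # large-sample median of a log-normal converges to exp(meanlog)
  set.seed(42)
  big <- data.frame(ch = rlnorm(1e5, log(250), 0.8))
  expect_equal(mfi(big, "ch"), 250, tolerance = 0.02)
})

test_that("MFI ratio and positivity calls follow the >= 3 convention", {
  expect_equal(mfi_ratio(300, 100), 3)
  expect_equal(mfi_ratio(100, 100), 1)
  expect_error(mfi_ratio(300, 0), "> 0")
  expect_true(call_positive(3))        # inclusive threshold
  expect_false(call_positive(2.99))
  expect_true(call_positive(2.5, threshold = 2))
  # monotone in ratio and threshold
  expect_true(call_positive(3.5) >= call_positive(3))
  expect_true(call_positive(3, threshold = 2) >= call_positive(3, threshold = 4))
})

test_that("percent binding endpoints, low-signal flag and failure modes", {
  expect_equal(as.numeric(percent_binding(50, 50, 500, 50)), 0)
  expect_equal(as.numeric(percent_binding(500, 50, 500, 50)), 100)
  expect_equal(as.numeric(percent_binding(162.5, 50, 500, 50)), 25)
  neg <- percent_binding(40, 50, 500, 50)
  expect_lt(as.numeric(neg), 0)                 # reported as-is
  expect_true(attr(neg, "low_signal"))
  expect_error(percent_binding(100, 50, 50, 50), "background")
})

test_that("enhancement index endpoints and failure modes", {
  expect_equal(enhancement_index(500, 500, 50), 1)
  expect_equal(enhancement_index(1400, 500, 50), 3)
  expect_error(enhancement_index(500, 40, 50), "background")
})

test_that("the cross-blocking matrix categorises pairs and rejects duplicates", {
  res <- data.frame(
    primary = c("A", "A", "B", "B"), test = c("A", "B", "A", "B"),
    percent_binding = c(2, 101, 180, 1))
  m <- epitope_overlap_matrix(res)
  expect_equal(m$category["A", "A"], "blocked")
  expect_equal(m$category["A", "B"], "independent")
  expect_equal(m$category["B", "A"], "enhanced")
  expect_error(epitope_overlap_matrix(rbind(res, res[2, ])), "duplicate")
  # thresholds are configurable
  m2 <- epitope_overlap_matrix(res, blocked_lt = 0.5, enhanced_gt = 150)
  expect_equal(m2$category["A", "A"], "independent")
})

test_that("four antibodies with zero pairwise overlap are all independent", {
  names_ <- c("w", "x", "y", "z")
  abs_ <- lapply(names_, function(nm) {
    ov <- as.list(rep(0, 3)); names(ov) <- setdiff(names_, nm)
    antibody_model(nm, 0.6, 0.6, overlap = ov)
  })
  names(abs_) <- names_
  rows <- list()
  for (p in names_) for (t in names_) {
    sim <- simulate_blocking_experiment(abs_[[p]], abs_[[t]],
                                        isoform_profile(1000, 1000),
                                        n = 50, seed = 1, noiseless = TRUE)
    rows[[paste(p, t)]] <- blocking_result(sim)
  }
  m <- epitope_overlap_matrix(do.call(rbind, rows))
  offdiag <- m$category[row(m$category) != col(m$category)]
  expect_true(all(offdiag == "independent"))
  expect_true(all(diag(m$category) == "blocked"))
})
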