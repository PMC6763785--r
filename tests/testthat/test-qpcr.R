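amps <- amplicon_set(c("target", "HPRT"), c("T", "HPRT"))

abund <- function(targets, hprt = 1) {
  do.call(rbind, lapply(names(targets), function(s)
    data.frame(sample = s, class = c("T", "HPRT"),
               abundance = c(targets[[s]], hprt))))
}

test_that("CT simulation: censoring, efficiency-1 doubling, determinism", {
  m0 <- simulate_qpcr(abund(list(s = 0)), amps, replicate_sd = 0)
  expect_true(all(m0$censored[m0$amplicon == "target"]))
  expect_true(all(m0$ct[m0$amplicon == "target"] == 40))

  m <- simulate_qpcr(abund(list(a = 1, b = 2)), amps, replicate_sd = 0)
  cta <- unique(m$ct[m$sample == "a" & m$amplicon == "target"])
  ctb <- unique(m$ct[m$sample == "b" & m$amplicon == "target"])
  expect_equal(cta - ctb, 1)  # doubling the template saves one cycle

  expect_error(amplicon_set("x", "X", efficiency = 1.2), "\\(0, 1\\]")
  expect_error(simulate_qpcr(abund(list(a = 1)),
                             data.frame(amplicon = "x", target_class = "T",
                                        efficiency = 0)),
               "\\(0, 1\\]")
  a <- simulate_qpcr(abund(list(a = 1, b = 3)), amps, seed = 4)
  b <- simulate_qpcr(abund(list(a = 1, b = 3)), amps, seed = 4)
  expect_identical(a, b)
})

test_that("delta-delta-CT closed form, calibrator identity and plate-shift invariance", {
  meas <- data.frame(
    sample = rep(c("s", "cal"), each = 2),
    amplicon = rep(c("target", "HPRT"), 2),
    replicate = 1L,
    ct = c(20, 18, 22, 18))
  fc <- delta_delta_ct(meas, "HPRT", "cal")
  expect_equal(fc$delta_delta_ct[fc$sample == "s"], -2)
  expect_equal(fc$fold_change[fc$sample == "s"], 4)
  expect_equal(fc$fold_change[fc$sample == "cal"], 1)  # exactly

  # adding a constant to every CT of one sample cancels in ddCT
  shifted <- meas
  shifted$ct[shifted$sample == "s"] <- shifted$ct[shifted$sample == "s"] + 3.7
  fc2 <- delta_delta_ct(shifted, "HPRT", "cal")
  expect_equal(fc2$fold_change, fc$fold_change)

  expect_error(delta_delta_ct(meas[meas$amplicon != "HPRT", ], "HPRT",
                              "cal"), "reference gene")
})

test_that("replicates are averaged and censored CTs propagate a flag", {
  meas <- data.frame(
    sample = rep(c("s", "cal"), each = 4),
    amplicon = rep(rep(c("target", "HPRT"), each = 2), 2),
    replicate = rep(1:2, 4),
    ct = c(19, 21, 18, 18, 22, 22, 18, 18))
  fc <- delta_delta_ct(meas, "HPRT", "cal")
  expect_equal(fc$fold_change[fc$sample == "s"], 4)  # mean CT 20
  cens <- meas
  cens$censored <- c(TRUE, rep(FALSE, 7))
  fc2 <- delta_delta_ct(cens, "HPRT", "cal")
  expect_true(fc2$censored[fc2$sample == "s"])
  expect_true(is.na(fc2$fold_change[fc2$sample == "s"]))
})

test_that("a simulated abundance ratio round-trips through the qPCR analysis", {
  # noiseless, efficiency 1: the 8-fold simulated ratio is exact
  m <- simulate_qpcr(abund(list(s = 8, cal = 1)), amps, replicate_sd = 0)
  fc <- delta_delta_ct(m, "HPRT", "cal")
  expect_equal(fc$fold_change[fc$sample == "s"], 8, tolerance = 1e-12)

  # efficiency 0.98, replicate SD 0.2 cycles: within 15% across seeds
  amps98 <- amplicon_set(c("target", "HPRT"), c("T", "HPRT"),
                         efficiency = 0.98)
  folds <- vapply(1:100, function(s) {
    m <- simulate_qpcr(abund(list(s = 8, cal = 1)), amps98, seed = s,
                       replicate_sd = 0.2)
    fc <- delta_delta_ct(m, "HPRT", "cal")
    fc$fold_change[fc$sample == "s"]
  }, numeric(1))
  # per-seed spread reflects the 0.2-cycle well noise; the estimator is
  # unbiased, so the aggregate over seeds recovers the simulated ratio
  expect_equal(mean(folds), 8, tolerance = 0.15)
  expect_equal(median(folds), 8, tolerance = 0.15)
})

test_that("primer pairs map to the documented isoform classes", {
  expect_setequal(assign_amplicon("CD300f_SI4_F", "CD300f_Ex4_R"),
                  c("Isoform 4", "Isoform 6"))
  expect_setequal(assign_amplicon("CD300f_C_F", "CD300f_Ex4_R"),
                  c("Isoform 1", "Isoform 2", "Isoform 3", "Isoform 5",
                    "Isoform 7"))
  expect_equal(assign_amplicon("Fw_hHPRT1", "Rv_hHPRT1"), "reference")
  expect_error(assign_amplicon("CD300f_SI4_F", "Rv_hHPRT1"), "unknown")
  expect_equal(nrow(cd300f_primers()), 5)
})

test_that("the isoform-class contrast separates SI4-high from SI4-low groups", {
  set.seed(77)
  groups <- setNames(rep(c("hspc", "aml"), each = 5),
                     c(paste0("h", 1:5), paste0("a", 1:5)))
  targets <- as.list(setNames(
    c(0.05 * rlnorm(5, 0, 0.3), 1 * rlnorm(5, 0, 0.3), 1),
    c(names(groups), "cal")))
  m <- simulate_qpcr(abund(targets), amps, seed = 3)
  fc <- delta_delta_ct(m, "HPRT", "cal")
  res <- isoform_class_contrast(fc, groups)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, -1)  # HSPC-like below AML-like
  expect_error(isoform_class_contrast(fc, groups[groups == "aml"]),
               "two groups")
  one_each <- groups[c(1, 6)]
  expect_error(isoform_class_contrast(fc, one_each), "two observations")
})
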