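panel <- default_antibody_panel()

test_that("event simulation is deterministic and degenerate inputs are valid", {
  spec <- default_cohort_spec(n_events = 500)
  a <- simulate_event_table(spec, panel, seed = 11)
  b <- simulate_event_table(spec, panel, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_event_table(spec, panel, seed = 12)))

  empty <- simulate_event_table(default_cohort_spec(n_events = 0), panel,
                                seed = 1)
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty), names(a))
})

test_that("cohort and population specs reject invalid parameters", {
  expect_error(population_spec("p", list(CD45 = c(1, 0)),
                               isoform_profile(0, 0), 1),
               "scale parameter")
  p <- population_spec("p", list(CD45 = c(1, 1)), isoform_profile(0, 0), 0.5)
  expect_error(cohort_spec(list(p), 10), "sum to 1")
  # antibody channels must not collide with marker channels
  bad_pop <- population_spec("p", list("UP-D1" = c(1, 1)),
                             isoform_profile(0, 0), 1)
  expect_error(simulate_event_table(cohort_spec(list(bad_pop), 10), panel,
                                    seed = 1),
               "collide")
})

test_that("cells without CD300f give an MFI ratio near 1 for every antibody", {
  lymph <- population_spec(
    "lymphocyte", list(CD45 = c(log(5000), 0.3)),
    isoform_profile(0, 0), 1)
  ev <- simulate_event_table(cohort_spec(list(lymph), 20000), panel,
                             seed = 21)
  iso <- mfi(ev, "IgG1")
  for (ab in setdiff(names(panel), "IgG1")) {
    expect_equal(mfi_ratio(mfi(ev, ab), iso), 1, tolerance = 0.05)
  }
})

test_that("expected channel signal is affine in surface copy numbers", {
  # noiseless tables over a grid of (n_C, n_SI4): intensity must equal
  # autofluorescence + gain * (n_C * acc_C + n_SI4 * acc_SI4) exactly
  noise <- noise_spec(gain = 1.7)
  grid <- expand.grid(n_C = c(0, 200, 900), n_SI4 = c(0, 400, 1100))
  vals <- mapply(function(nc, ns) {
    pop <- population_spec("p", list(CD45 = c(1, 1)),
                           isoform_profile(nc, ns), 1)
    ev <- simulate_event_table(cohort_spec(list(pop), 5, noise), panel,
                               seed = 1, noiseless = TRUE)
    ev[["DCR-2"]][1]
  }, grid$n_C, grid$n_SI4)
  fit <- lm(vals ~ grid$n_C + grid$n_SI4)
  ab <- panel[["DCR-2"]]
  expect_equal(unname(coef(fit)[2]), noise$gain * ab$acc_C,
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)[3]), noise$gain * ab$acc_SI4,
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), exp(noise$af_meanlog),
               tolerance = 1e-8)
})

test_that("sampled surface totals respect the 10^4 copies-per-cell cap", {
  prof <- isoform_profile(6000, 6000, sdlog = 1)
  pop <- population_spec("p", list(CD45 = c(1, 1)), prof, 1)
  ev <- simulate_event_table(cohort_spec(list(pop), 5000,
                                         noise_spec(cv = 0)),
                             panel, seed = 5)
  # with accessibility <= 1 the specific DCR-2 signal bounds total copies
  ab <- panel[["DCR-2"]]
  sig <- ev[["DCR-2"]] - 0  # autofluorescence is positive, so this is loose
  expect_true(all(sig <= 1e4 * max(ab$acc_C, ab$acc_SI4) + 1e4))
  # and direct check through a saturating-accessibility antibody
  full <- antibody_model("full", 1, 1)
  ev2 <- simulate_event_table(
    cohort_spec(list(pop), 5000, noise_spec(af_meanlog = log(1e-6),
                                            af_sdlog = 1e-3, cv = 0)),
    list(full = full, iso = antibody_model("iso", 0, 0, is_isotype = TRUE)),
    seed = 5)
  expect_true(all(ev2$full <= 1e4 + 1))
})
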