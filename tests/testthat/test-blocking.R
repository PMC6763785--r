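profile <- isoform_profile(800, 1600)

test_that("noiseless percent binding follows the closed form 100*(1-omega)*e", {
  for (omega in c(0, 0.25, 0.5, 0.75, 1)) {
    for (e in c(1, 2, 3)) {
      pr <- make_pair(omega, e)
      sim <- simulate_blocking_experiment(pr$primary, pr$test, profile,
                                          n = 200, seed = 3,
                                          noiseless = TRUE)
      br <- blocking_result(sim)
      expect_equal(br$percent_binding, 100 * (1 - omega) * e,
                   tolerance = 1e-10)
      expect_equal(br$fraction_bound, br$percent_binding / 100)
    }
  }
})

test_that("complete overlap leaves only background; zero overlap leaves binding intact", {
  pr <- make_pair(1)
  sim <- simulate_blocking_experiment(pr$primary, pr$test, profile,
                                      n = 100, seed = 2, noiseless = TRUE)
  expect_equal(sim$test_given_primary, sim$background_primary)
  pr0 <- make_pair(0)
  sim0 <- simulate_blocking_experiment(pr0$primary, pr0$test, profile,
                                       n = 100, seed = 2, noiseless = TRUE)
  expect_equal(mfi(sim0$test_given_primary, "test"),
               mfi(sim0$test_given_isotype, "test"))
})

test_that("SI4-specific enhancement is larger on an SI4-rich profile", {
  primary <- antibody_model("primary", 0.8, 0.9,
                            overlap = list(test = 0),
                            enhancer_of = list(test = c(1, 3)))
  test <- antibody_model("test", 0.7, 0.8, overlap = list(primary = 0))
  pb <- function(prof) {
    sim <- simulate_blocking_experiment(primary, test, prof, n = 100,
                                        seed = 1, noiseless = TRUE)
    blocking_result(sim)$percent_binding
  }
  expect_equal(pb(isoform_profile(1000, 0)), 100)     # no SI4, no effect
  expect_gt(pb(isoform_profile(0, 1000)), pb(isoform_profile(500, 500)))
  expect_equal(pb(isoform_profile(0, 1000)), 300)     # pure SI4: e_SI4
})

test_that("enhancement index is nondecreasing in the SI4 fraction", {
  primary <- antibody_model("primary", 0.8, 0.9,
                            overlap = list(test = 0),
                            enhancer_of = list(test = c(1.5, 4)))
  test <- antibody_model("test", 0.7, 0.8, overlap = list(primary = 0))
  idx <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    sim <- simulate_blocking_experiment(
      primary, test, isoform_profile(2000 * (1 - f), 2000 * f),
      n = 100, seed = 1, noiseless = TRUE)
    m <- vapply(sim, mfi, numeric(1), channel = "test")
    enhancement_index(m[["test_given_primary"]],
                      m[["test_given_isotype"]],
                      m[["background_isotype"]])
  }, numeric(1))
  expect_true(all(diff(idx) >= -1e-12))
  expect_equal(idx[1], 1.5, tolerance = 1e-10)
  expect_equal(idx[5], 4, tolerance = 1e-10)
})

test_that("blocking simulation validates inputs and is seed-deterministic", {
  pr <- make_pair(0.5)
  expect_error(simulate_blocking_experiment(pr$primary, pr$test, profile,
                                            n = -1), ">= 0")
  a <- simulate_blocking_experiment(pr$primary, pr$test, profile,
                                    n = 500, seed = 9)
  b <- simulate_blocking_experiment(pr$primary, pr$test, profile,
                                    n = 500, seed = 9)
  expect_identical(a, b)
})
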