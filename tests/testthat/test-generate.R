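test_that("identical config and seed give byte-identical datasets", {
  cfg <- generator_config(n = 500, target_prevalence = 0.1, pr = 2,
                          exposure_prevalence = 0.5)
  d1 <- generate_subjects(cfg, seed = 123)
  d2 <- generate_subjects(cfg, seed = 123)
  expect_identical(d1, d2)
  d3 <- generate_subjects(cfg, seed = 124)
  expect_false(identical(d1, d3))
})

test_that("infeasible configurations are refused before any draw", {
  expect_error(
    generator_config(n = 100, target_prevalence = 0.9, pr = 1.3,
                     age_effects = c(0.1, 0.2, 0.3),
                     exposure_prevalence = 0.5),
    "infeasible")
})

test_that("the study age distribution reproduces the published shares", {
  p <- age_pmf("study")
  ages <- 18:56
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(ages * p), 28.2, tolerance = 1e-9)
  shares <- tapply(p, cut(ages, c(18, 26, 30, 35, 57), right = FALSE), sum)
  expect_equal(as.numeric(100 * shares), c(41.9, 24.0, 14.0, 20.2),
               tolerance = 0.005)  # published shares sum to 100.1%
})

test_that("a null exposure effect yields a fitted PR near 1 at large n", {
  cfg <- generator_config(n = 100000, target_prevalence = 0.1, pr = 1,
                          exposure_prevalence = 0.5)
  d <- generate_subjects(cfg, seed = 2024)
  des <- build_design(d, "outcome", "depression")
  f <- fit_negbin(des$y, des$X)
  expect_gt(exp(f$beta[2]), 0.97)
  expect_lt(exp(f$beta[2]), 1.03)
})

test_that("without confounding, crude and MH both recover the true PR", {
  cfg <- generator_config(n = 100000, target_prevalence = 0.1, pr = 2,
                          exposure_prevalence = 0.5)
  d <- generate_subjects(cfg, seed = 99)
  crude <- crude_pr(subject_table(d, "outcome", "depression"))
  mh <- mh_pr(subject_table(d, "outcome", "depression",
                            strata = "age_group"))
  expect_equal(crude$point, 2, tolerance = 0.05)
  expect_equal(mh$point, 2, tolerance = 0.05)
})

test_that("empirical moments approach the calibrated targets as 1/sqrt(n)", {
  cfg_small <- generator_config(n = 2000, target_prevalence = 0.2, pr = 2,
                                exposure_prevalence = 0.5)
  cfg_big <- cfg_small; cfg_big$n <- 50000
  for (s in 1:3) {
    p_small <- mean(generate_subjects(cfg_small, seed = s)$outcome)
    p_big <- mean(generate_subjects(cfg_big, seed = s)$outcome)
    expect_lt(abs(p_small - 0.2), 4 * sqrt(0.2 * 0.8 / 2000))
    expect_lt(abs(p_big - 0.2), 4 * sqrt(0.2 * 0.8 / 50000))
  }
})

test_that("positive age-exposure and age-outcome effects push the crude PR
          above the MH PR", {
  diffs <- vapply(1:5, function(s) {
    d <- generate_study(5810, seed = s)
    crude_pr(subject_table(d, "cigarette", "depression"))$point -
      mh_pr(subject_table(d, "cigarette", "depression",
                          strata = "age_group"))$point
  }, 0)
  expect_true(all(diffs > 0))
})

test_that("latent frailty is off by default and shifts the marginal rate
          upward when enabled", {
  cfg <- generator_config(n = 30000, target_prevalence = 0.15, pr = 2,
                          exposure_prevalence = 0.5)
  expect_equal(cfg$frailty_sd, 0)  # off by default
  cfg$frailty_sd <- 0.5
  d <- generate_subjects(cfg, seed = 55)
  # the multiplier is mean-zero on the log scale, so its expectation
  # exceeds 1 and the marginal prevalence rises above the target
  expect_gt(mean(d$outcome), 0.15)
  expect_lt(mean(d$outcome), 0.25)
  expect_identical(d, generate_subjects(cfg, seed = 55))
})

test_that("the recovery harness completes and reports on degenerate
          small samples", {
  cfg <- generator_config(n = 50, target_prevalence = 0.1, pr = 2,
                          exposure_prevalence = 0.5)
  res <- recovery_experiment(cfg, 10, models = c("negative_log_binomial",
                                                 "log_binomial"),
                             seed = 3)
  expect_equal(nrow(res), 2)
  expect_true(all(res$n_converged + res$n_nonconverged == 10))
})

test_that("study presets expose the documented scope limitation", {
  scope <- study_emulation_scope()
  expect_match(scope, "confidential")
  expect_match(scope, "cannot be reproduced")
})
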