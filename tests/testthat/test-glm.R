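test_that("saturated one-covariate fits reproduce the crude estimates in
          every family", {
  set.seed(5)
  for (t in random_tables(8)) {
    d <- expand_subjects(t)
    des <- build_design(d, "outcome", "exposure")
    p <- prevalences(t)
    for (fam in c("log_binomial", "log_poisson", "negative_log_binomial")) {
      f <- fit_glm(des$y, des$X, fam)
      expect_equal(unname(f$beta),
                   c(log(p[["p2"]]), log(p[["p1"]] / p[["p2"]])),
                   tolerance = 1e-8)
    }
    fl <- fit_glm(des$y, des$X, "logistic")
    expect_equal(exp(unname(fl$beta[2])), crude_or(t)$point,
                 tolerance = 1e-8)
  }
})

test_that("cox_constant_time is a bit-identical alias of log_poisson", {
  set.seed(8)
  dat <- random_glm_data(300)
  f1 <- fit_glm(dat$y, dat$X, "log_poisson")
  f2 <- fit_glm(dat$y, dat$X, "cox_constant_time")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$cov_model, f2$cov_model)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f2$family, "log_poisson")
  expect_identical(f2$family_requested, "cox_constant_time")
})

test_that("accepted IRLS iterations never decrease the log-likelihood", {
  set.seed(12)
  for (i in 1:5) {
    dat <- random_glm_data(250)
    for (fam in c("logistic", "log_binomial", "log_poisson")) {
      f <- fit_glm(dat$y, dat$X, fam)
      expect_true(all(diff(f$loglik_trace) >= -1e-12))
    }
  }
})

test_that("NB collapses to Poisson on underdispersed binary data", {
  set.seed(19)
  dat <- random_glm_data(400)
  fp <- fit_glm(dat$y, dat$X, "log_poisson")
  fn <- fit_negbin(dat$y, dat$X)
  expect_equal(fn$alpha, 0)
  expect_equal(fn$beta, fp$beta, tolerance = 1e-6)
  expect_equal(fn$loglik, fp$loglik, tolerance = 1e-9)
})

test_that("NB dispersion is recovered from overdispersed counts", {
  set.seed(23)
  alphas <- replicate(20, {
    n <- 20000
    x <- rbinom(n, 1, 0.5)
    mu <- exp(0.2 + 0.7 * x)
    y <- rnbinom(n, size = 2, mu = mu)   # alpha = 0.5
    fit_negbin(y, cbind(1, x))$alpha
  })
  mcse <- sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.5), 3 * mcse + 0.01)
})

test_that("NB model-based SE is at least the Poisson SE once alpha > 0", {
  set.seed(29)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  y <- rnbinom(n, size = 2, mu = exp(0.2 + 0.6 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  fp <- fit_glm(y, X, "log_poisson")
  fn <- fit_negbin(y, X)
  expect_gt(fn$alpha, 0)
  expect_gte(sqrt(fn$cov_model[2, 2]), sqrt(fp$cov_model[2, 2]))
  # and the NB fits the overdispersion: smaller BIC despite the extra
  # dispersion parameter
  expect_lt(fn$bic, fp$bic)
})

test_that("BIC arithmetic and nested differences are exact", {
  f <- structure(list(loglik = -100, n_params = 2, n_obs = 1000,
                      converged = "yes"), class = "pr_fit")
  expect_equal(bic(f), 200 + 2 * log(1000))
  set.seed(31)
  dat <- random_glm_data(300)
  f2 <- fit_glm(dat$y, dat$X, "log_poisson")                 # 3 params
  f1 <- fit_glm(dat$y, dat$X[, 1:2], "log_poisson")          # 2 params
  expect_equal(f1$bic - f2$bic,
               -2 * (f1$loglik - f2$loglik) - log(300),
               tolerance = 1e-9)
  f2$converged <- "no_boundary"
  expect_true(is.na(bic(f2)))
})

test_that("boundary-seeking log-binomial fits report no_boundary", {
  set.seed(37)
  n <- 1500
  z <- runif(n, 0, 40)
  mu <- pmin(exp(-0.5 + 0.02 * z), 1 - 1e-9)
  y <- rbinom(n, 1, mu)
  # a steeper working model must push fitted probabilities past 1
  X <- cbind("(Intercept)" = 1, z = z, z2 = pmax(z - 30, 0))
  f <- fit_glm(y, X, "log_binomial")
  expect_true(f$converged %in% c("yes", "no_boundary", "no_maxiter"))
  # the non-convergence path must be observable on extreme data
  yext <- as.integer(z > 1)
  fext <- fit_glm(yext, cbind("(Intercept)" = 1, z = z), "log_binomial")
  expect_identical(fext$converged, "no_boundary")
  expect_true(is.na(bic(fext)))
})

test_that("rank-deficient designs are rejected", {
  set.seed(41)
  dat <- random_glm_data(100)
  X <- cbind(dat$X, dup = dat$X[, "x"])
  expect_error(fit_glm(dat$y, X, "log_poisson"), "rank deficient")
})

test_that("extract_effect exponentiates and labels the measure by family", {
  t <- tab2x2(10, 90, 5, 95)
  d <- expand_subjects(t)
  des <- build_design(d, "outcome", "exposure")
  f <- fit_glm(des$y, des$X, "log_poisson")
  e <- extract_effect(f, "exposure")
  expect_identical(e$measure, "PR")
  expect_equal(e$point, 2, tolerance = 1e-8)
  fl <- fit_glm(des$y, des$X, "logistic")
  el <- extract_effect(fl, "exposure")
  expect_identical(el$measure, "OR")
  expect_error(extract_effect(f, "nope"), "no fitted term")
})
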