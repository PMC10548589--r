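test_that("crude PR point estimate and delta-method SE are correct", {
  expect_equal(crude_pr(tab2x2(10, 10, 10, 10))$point, 1)
  e <- crude_pr(tab2x2(10, 90, 5, 95))
  expect_equal(e$point, 2)
  expect_equal(e$se_log, sqrt(1 / 10 - 1 / 100 + 1 / 5 - 1 / 100))
  expect_equal(e$se_log, sqrt(0.28), tolerance = 1e-12)
})

test_that("delta-method SE agrees with the bootstrap SD of ln PR", {
  # Nonparametric bootstrap of subjects within exposure groups reduces
  # to binomial resampling of the case counts. The delta method is a
  # first-order approximation: agreement is tight when counts are
  # moderate, and only first-order (ln PR is skewed) at very small
  # counts such as a = 10, c = 5.
  set.seed(424242)
  B <- 200000
  boot_sd <- function(n1, a, n0, c_) {
    as_ <- rbinom(B, n1, a / n1)
    cs_ <- rbinom(B, n0, c_ / n0)
    v <- log((as_ / n1) / (cs_ / n0))
    sd(v[is.finite(v)])
  }
  big <- boot_sd(1000, 100, 1000, 50)
  expect_equal(crude_pr(tab2x2(100, 900, 50, 950))$se_log, big,
               tolerance = 0.025)
  small <- boot_sd(100, 10, 100, 5)
  expect_equal(crude_pr(tab2x2(10, 90, 5, 95))$se_log, small,
               tolerance = 0.15)
})

test_that("crude OR matches its closed form and Woolf SE", {
  expect_equal(crude_or(tab2x2(10, 10, 10, 10))$point, 1)
  e <- crude_or(tab2x2(10, 90, 5, 95))
  expect_equal(e$point, (10 * 95) / (90 * 5))
  expect_equal(e$se_log, sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95))
})

test_that("zero cells give an explicit undefined status, never infinity", {
  e <- crude_pr(tab2x2(10, 90, 0, 100))
  expect_identical(e$status, "undefined")
  expect_match(e$note, "cell c")
  expect_true(is.na(e$point))
  e2 <- crude_or(tab2x2(10, 0, 5, 95))
  expect_identical(e2$status, "undefined")
  expect_match(e2$note, "b")
  expect_error(tab2x2(-1, 2, 3, 4), "non-negative")
  expect_error(tab2x2(1.5, 2, 3, 4), "integer")
})

test_that("continuity correction is off by default and adds 0.5 on demand", {
  t0 <- tab2x2(10, 90, 0, 100)
  expect_identical(crude_pr(t0)$status, "undefined")
  e <- crude_pr(t0, continuity = TRUE)
  expect_identical(e$status, "ok")
  expect_equal(e$point, (10.5 / 101) / (0.5 / 101))
})

test_that("Wald CI uses the exact normal quantile and round-trips", {
  ci <- wald_ci(2, 0)
  expect_equal(unname(ci), c(2, 2))
  set.seed(11)
  for (i in 1:25) {
    point <- exp(rnorm(1))
    se <- runif(1, 0.01, 1.5)
    lvl <- runif(1, 0.5, 0.99)
    ci <- wald_ci(point, se, lvl)
    z <- qnorm((1 + lvl) / 2)
    # back-solve the SE from the interval
    expect_equal(log(ci[["ci_high"]] / ci[["ci_low"]]) / (2 * z), se,
                 tolerance = 1e-12)
    expect_true(ci[["ci_low"]] <= point && point <= ci[["ci_high"]])
  }
})

test_that("OR exceeds PR exactly by the inherent bias factor when PR > 1", {
  set.seed(21)
  for (t in random_tables(30)) {
    p <- prevalences(t)
    pr <- crude_pr(t)$point
    or <- crude_or(t)$point
    expect_equal(or, pr * (1 - p[["p2"]]) / (1 - p[["p1"]]),
                 tolerance = 1e-12)
    if (pr > 1) expect_gte(or, pr)
  }
})

test_that("MH on a single stratum equals the crude estimate exactly", {
  t <- tab2x2(17, 83, 9, 121)
  e1 <- mh_pr(stratified_tables(list(t)))
  e2 <- crude_pr(t)
  expect_equal(e1$point, e2$point, tolerance = 1e-14)
  expect_equal(e1$se_log, e2$se_log, tolerance = 1e-12)
})

test_that("MH over identical strata equals the pooled crude PR", {
  t <- tab2x2(10, 90, 5, 95)
  e <- mh_pr(stratified_tables(list(t, t)))
  expect_equal(e$point, 2, tolerance = 1e-12)
  pooled <- crude_pr(tab2x2(20, 180, 10, 190))
  expect_equal(e$point, pooled$point, tolerance = 1e-12)
})

test_that("MH pooling matches a direct weighted-sum oracle and removes
          confounding in the right direction", {
  s <- stratified_tables(list(tab2x2(30, 70, 10, 90),
                              tab2x2(5, 95, 20, 180)))
  e <- mh_pr(s)
  # independent direct computation of the MH sums
  num <- 30 * 100 / 200 + 5 * 200 / 300
  den <- 10 * 100 / 200 + 20 * 100 / 300
  expect_equal(e$point, num / den, tolerance = 1e-12)
  # value frozen from statsmodels StratifiedTable.riskratio_pooled
  expect_equal(e$point, 1.5714285714285712, tolerance = 1e-12)
  # exposure is concentrated in the high-risk stratum: crude exceeds MH
  pooled <- crude_pr(tab2x2(35, 165, 30, 270))
  expect_gt(pooled$point, e$point)
})

test_that("Greenland-Robins SE matches the sampling SD of ln MH-PR", {
  set.seed(99)
  B <- 1500
  lnpr <- ses <- numeric(B)
  for (i in seq_len(B)) {
    a1 <- rbinom(1, 100, 0.30); c1 <- rbinom(1, 100, 0.20)
    a2 <- rbinom(1, 150, 0.12); c2 <- rbinom(1, 300, 0.08)
    s <- stratified_tables(list(tab2x2(a1, 100 - a1, c1, 100 - c1),
                                tab2x2(a2, 150 - a2, c2, 300 - c2)))
    e <- mh_pr(s)
    lnpr[i] <- log(e$point)
    ses[i] <- e$se_log
  }
  expect_equal(mean(ses), sd(lnpr), tolerance = 0.05)
})

test_that("subject expansion and collapse are exact inverses", {
  t <- tab2x2(7, 13, 3, 27)
  d <- expand_subjects(t)
  expect_equal(nrow(d), 50)
  t2 <- subject_table(d, "outcome", "exposure")
  expect_identical(unclass(t)[c("a", "b", "c", "d")],
                   unclass(t2)[c("a", "b", "c", "d")])
})
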