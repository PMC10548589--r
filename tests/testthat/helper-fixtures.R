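# Random 2x2 tables with all cells positive
random_tables <- function(k, nmax = 400) {
  lapply(seq_len(k), function(i) {
    repeat {
      n1 <- sample(20:nmax, 1)
      n0 <- sample(20:nmax, 1)
      a <- rbinom(1, n1, runif(1, 0.05, 0.6))
      c_ <- rbinom(1, n0, runif(1, 0.05, 0.6))
      if (a > 0 && c_ > 0 && a < n1 && c_ < n0)
        return(tab2x2(a, n1 - a, c_, n0 - c_))
    }
  })
}

# Random subject-level dataset from a log-link model with bounded mu,
# where the log-binomial MLE is comfortably interior.
random_glm_data <- function(n) {
  x <- rbinom(n, 1, 0.4)
  z <- rnorm(n)
  mu <- pmin(exp(log(0.15) + 0.5 * x + 0.15 * z), 0.8)
  list(y = rbinom(n, 1, mu),
       yc = rnbinom(n, size = 2, mu = exp(0.3 + 0.5 * x + 0.2 * z)),
       X = cbind("(Intercept)" = 1, x = x, z = z))
}

tight_glm_control <- function() stats::glm.control(epsilon = 1e-12,
                                                   maxit = 100)
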