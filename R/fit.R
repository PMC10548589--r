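#' @name fit_glm
#' @rdname fit_glm
NULL

FAMILIES <- c("logistic", "log_binomial", "log_poisson",
              "cox_constant_time", "negative_log_binomial")

resolve_family <- function(family) {
  family <- match.arg(family, FAMILIES)
  # Cox regression at constant time and the log-Poisson GLM yield the same
  # estimating equations for cross-sectional PR estimation; the alias
  # resolves to the identical code path (bit-identical results).
  if (family == "cox_constant_time") "log_poisson" else family
}

loglik_fun <- function(family, alpha = 0) {
  switch(family,
    logistic = function(y, mu) {
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      sum(y * log(mu) + (1 - y) * log(1 - mu))
    },
    log_binomial = function(y, mu) {
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      sum(y * log(mu) + (1 - y) * log(1 - mu))
    },
    log_poisson = function(y, mu) {
      mu <- pmax(mu, 1e-12)
      sum(y * log(mu) - mu - lgamma(y + 1))
    },
    negative_log_binomial = function(y, mu) nb_loglik(y, mu, alpha)
  )
}

# NB2 log-likelihood (variance mu + alpha mu^2); continuous at alpha -> 0
# where it collapses to the Poisson log-likelihood.
nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-12)
  if (alpha < 1e-10)
    return(sum(y * log(mu) - mu - lgamma(y + 1)))
  r <- 1 / alpha
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
      y * log(alpha * mu) - (y + r) * log1p(alpha * mu))
}

irls_weights <- function(family, mu, alpha = 0) {
  switch(family,
    logistic = mu * (1 - mu),
    log_binomial = mu / pmax(1 - mu, 1e-12),
    log_poisson = mu,
    negative_log_binomial = mu / (1 + alpha * mu)
  )
}

mu_valid <- function(family, mu) {
  if (any(!is.finite(mu))) return(FALSE)
  if (family %in% c("log_binomial", "logistic")) all(mu < 1 - 1e-10) else TRUE
}

linkinv <- function(family, eta) {
  if (family == "logistic") stats::plogis(eta) else exp(pmin(eta, 700))
}

init_beta <- function(y, X, family) {
  # least-squares fit on the linearized response
  mu0 <- (y + mean(y)) / 2
  mu0 <- pmin(pmax(mu0, 1e-3), 1 - 1e-3)
  eta0 <- if (family == "logistic") stats::qlogis(mu0) else log(mu0)
  qr.coef(qr(X), eta0)
}

# Core iteratively reweighted least squares (Fisher scoring) with
# step-halving so accepted iterations never decrease the log-likelihood.
irls <- function(y, X, family, alpha = 0, tol = 1e-6, max_iter = 100,
                 beta_init = NULL) {
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank deficient")
  ll <- loglik_fun(family, alpha)
  beta <- if (is.null(beta_init)) init_beta(y, X, family) else beta_init
  eta <- drop(X %*% beta)
  mu <- linkinv(family, eta)
  if (!mu_valid(family, mu)) {
    # pull an infeasible start toward the feasible constant-rate point
    # (intercept = log mean(y), slopes 0), which satisfies mu < 1
    feas <- numeric(p)
    feas[1] <- log(max(min(mean(y), 1 - 1e-4), 1e-4))
    for (h in 1:60) {
      beta <- (beta + feas) / 2
      eta <- drop(X %*% beta); mu <- linkinv(family, eta)
      if (mu_valid(family, mu)) break
    }
    if (!mu_valid(family, mu)) {
      beta <- feas
      eta <- drop(X %*% beta); mu <- linkinv(family, eta)
    }
    if (!mu_valid(family, mu))
      stop("cannot find feasible starting values (is the first design ",
           "column an intercept?)")
  }
  cur_ll <- ll(y, mu)
  ll_trace <- cur_ll
  converged <- FALSE
  stalled <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    w <- pmax(irls_weights(family, mu, alpha), 1e-12)
    z <- if (family == "logistic") eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
         else eta + (y - mu) / pmax(mu, 1e-12)
    sw <- sqrt(w)
    fit_wls <- qr.coef(qr(X * sw), z * sw)
    dir <- fit_wls - beta
    step <- 1
    accepted <- FALSE
    for (h in 1:50) {
      cand <- beta + step * dir
      eta_c <- drop(X %*% cand)
      mu_c <- linkinv(family, eta_c)
      if (mu_valid(family, mu_c)) {
        ll_c <- ll(y, mu_c)
        if (is.finite(ll_c) && ll_c >= cur_ll - 1e-12) { accepted <- TRUE; break }
      }
      step <- step / 2
    }
    if (!accepted) { stalled <- TRUE; break }
    delta <- max(abs(cand - beta))
    rel_dev <- abs(ll_c - cur_ll) / (abs(cur_ll) + 0.1)
    beta <- cand; eta <- eta_c; mu <- mu_c; cur_ll <- ll_c
    ll_trace <- c(ll_trace, cur_ll)
    if (delta < tol && rel_dev < tol) { converged <- TRUE; break }
  }
  pinned <- family == "log_binomial" && max(mu) > 1 - 1e-8
  status <- if (pinned) "no_boundary"
            else if (converged) "yes"
            else "no_maxiter"
  w <- pmax(irls_weights(family, mu, alpha), 1e-12)
  info <- crossprod(X * sqrt(w))            # expected (Fisher) information
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(beta = beta, cov_model = cov, loglik = cur_ll, mu = mu,
       converged = status, iterations = iter, stalled = stalled,
       loglik_trace = ll_trace)
}

#' Fit a prevalence-ratio regression model by maximum likelihood
#'
#' Iteratively reweighted least squares (Fisher scoring) with
#' step-halving, so the log-likelihood never decreases across accepted
#' iterations. Convergence requires both the maximum coefficient change
#' and the relative deviance change to fall below `tol` (default 1e-6).
#' For the log-link binomial family the fitted probabilities are kept
#' inside (0, 1) by step-halving; iterates pinned against the boundary
#' are reported as `converged = "no_boundary"` - non-convergence is
#' first-class data here, never an exception.
#'
#' Families: `"logistic"` (OR scale), `"log_binomial"`, `"log_poisson"`,
#' `"cox_constant_time"` (a documented alias of log-Poisson: at constant
#' time the Cox partial-likelihood estimating equations coincide with the
#' log-Poisson score, so the two labels resolve to the identical fit) and
#' `"negative_log_binomial"` (delegates to [fit_negbin()]).
#'
#' For Poisson-type families on binary outcomes the likelihood is a
#' working likelihood for ratio estimation (`y! = 1`).
#'
#' @param y Response vector (0/1 for binomial-type families, non-negative
#'   integer counts allowed for Poisson / negative binomial).
#' @param X Design matrix of full column rank (see [build_design()]).
#' @param family One of the family strings above.
#' @param tol Convergence tolerance (epsilon) for both criteria.
#' @param max_iter Maximum number of IRLS iterations.
#' @return A list of class `"pr_fit"`: `beta`, `cov_model` (model-based
#'   covariance from the expected information), `loglik`, `bic`, `alpha`
#'   (NB dispersion, `NA` for other families), `converged`
#'   (`"yes"`, `"no_boundary"` or `"no_maxiter"`), `n_obs`, `n_params`,
#'   `iterations`, `family`, plus `y`, `X`, fitted `mu` and
#'   `loglik_trace` (log-likelihood at each accepted iteration, monotone
#'   non-decreasing by construction) for variance post-processing and
#'   diagnostics.
#' @examples
#' d <- expand_subjects(tab2x2(10, 90, 5, 95))
#' des <- build_design(d, "outcome", "exposure")
#' f <- fit_glm(des$y, des$X, "log_poisson")
#' exp(f$beta["exposure"])  # = crude PR = 2
#' @export
fit_glm <- function(y, X, family, tol = 1e-6, max_iter = 100) {
  fam_req <- match.arg(family, FAMILIES)
  fam <- resolve_family(fam_req)
  if (fam == "negative_log_binomial")
    return(fit_negbin(y, X, tol = tol, max_iter = max_iter))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y < 0)) stop("invalid response")
  if (fam %in% c("logistic", "log_binomial") && !all(y %in% c(0, 1)))
    stop("binomial-type families require a binary 0/1 response")
  if (length(y) < ncol(X)) stop("fewer observations than parameters")
  res <- irls(y, X, fam, tol = tol, max_iter = max_iter)
  finish_fit(res, y, X, fam, fam_req, alpha = NA_real_,
             n_params = ncol(X), tol = tol)
}

finish_fit <- function(res, y, X, fam, fam_req, alpha, n_params, tol,
                       outer_iterations = NULL) {
  fit <- list(beta = res$beta, cov_model = res$cov_model,
              loglik = res$loglik, alpha = alpha,
              converged = res$converged,
              n_obs = length(y), n_params = n_params,
              iterations = if (is.null(outer_iterations)) res$iterations
                           else outer_iterations,
              family = fam, family_requested = fam_req,
              mu = res$mu, y = y, X = X, tol = tol,
              loglik_trace = res$loglik_trace)
  fit$bic <- if (fit$converged == "yes")
    -2 * fit$loglik + n_params * log(length(y)) else NA_real_
  class(fit) <- "pr_fit"
  fit
}

#' @export
print.pr_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s), n = %d, loglik = %.4f, BIC = %.4f\n",
              x$family_requested, x$converged, x$n_obs, x$loglik,
              if (is.na(x$bic)) NA else x$bic))
  if (!is.na(x$alpha)) cat(sprintf("dispersion alpha = %.6g\n", x$alpha))
  print(cbind(beta = x$beta, se = sqrt(diag(x$cov_model))))
  invisible(x)
}

#' Fit the negative log-binomial (NB2 log-link) model
#'
#' Alternating maximization: IRLS for the coefficients given the
#' dispersion `alpha`, and one-dimensional likelihood maximization for
#' `alpha` given the coefficients, on the NB2 likelihood
#' (variance `mu + alpha * mu^2`). `alpha` is constrained to be
#' non-negative; when the dispersion score at zero is non-positive the
#' fit collapses to the Poisson boundary (`alpha = 0`), at which the
#' log-likelihood is continuous. Joint convergence requires coefficient,
#' dispersion and deviance changes below `tol`.
#'
#' The model-based covariance treats `alpha` as fixed at its estimate
#' (profile covariance), the convention of mainstream NB regression
#' software; `alpha` is counted as a model parameter in the BIC.
#'
#' @inheritParams fit_glm
#' @param alpha_cap Upper bound on the dispersion; estimates diverging to
#'   the cap are reported as `converged = "no_boundary"`.
#' @return A `"pr_fit"` object (see [fit_glm()]) with `alpha` set.
#' @export
fit_negbin <- function(y, X, tol = 1e-6, max_iter = 100, alpha_cap = 1e6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y < 0)) stop("invalid response")
  if (length(y) < ncol(X) + 1) stop("fewer observations than parameters")
  fam <- "negative_log_binomial"
  # start from the Poisson fit (alpha = 0)
  res <- irls(y, X, "log_poisson", tol = tol, max_iter = max_iter)
  mu <- res$mu
  score0 <- 0.5 * sum((y - mu)^2 - y)   # dispersion score at alpha = 0+
  if (score0 <= 0) {
    res$loglik <- nb_loglik(y, mu, 0)
    return(finish_fit(res, y, X, fam, fam, alpha = 0,
                      n_params = ncol(X) + 1, tol = tol))
  }
  alpha <- 0.01
  beta <- res$beta
  outer <- 0
  status <- "no_maxiter"
  ll_old <- -Inf
  repeat {
    outer <- outer + 1
    opt <- stats::optimize(function(la) nb_loglik(y, mu, exp(la)),
                           interval = c(log(1e-8), log(alpha_cap)),
                           maximum = TRUE, tol = 1e-9)
    alpha_new <- exp(opt$maximum)
    if (nb_loglik(y, mu, 0) >= opt$objective) alpha_new <- 0
    res <- irls(y, X, fam, alpha = alpha_new, tol = tol,
                max_iter = max_iter, beta_init = beta)
    ll_new <- res$loglik
    d_beta <- max(abs(res$beta - beta))
    d_alpha <- abs(alpha_new - alpha) / (1 + alpha)
    rel_dev <- abs(ll_new - ll_old) / (abs(ll_new) + 0.1)
    beta <- res$beta; mu <- res$mu; alpha <- alpha_new; ll_old <- ll_new
    if (alpha > alpha_cap * (1 - 1e-6)) { status <- "no_boundary"; break }
    if (d_beta < tol && d_alpha < tol && rel_dev < tol) {
      status <- res$converged
      break
    }
    if (outer >= max_iter) { status <- "no_maxiter"; break }
  }
  res$converged <- status
  finish_fit(res, y, X, fam, fam, alpha = alpha,
             n_params = ncol(X) + 1, tol = tol, outer_iterations = outer)
}

#' Bayesian information criterion of a fit
#'
#' `-2 loglik + k log(n)`, with the NB dispersion counted as a parameter.
#' Lower values indicate the preferred model. Undefined (`NA`) for
#' non-converged fits, which are reported as missing in comparisons.
#'
#' @param fit A `"pr_fit"` object.
#' @return The BIC value, or `NA_real_` if the fit did not converge.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "pr_fit"))
  if (fit$converged != "yes") return(NA_real_)
  -2 * fit$loglik + fit$n_params * log(fit$n_obs)
}

#' Extract a ratio effect estimate from a fitted model
#'
#' Exponentiates the coefficient of `term`: for the logistic family the
#' result is an odds ratio, for all log-link families a prevalence ratio
#' (`exp(beta) = PR`). The SE is taken from the supplied covariance
#' (model-based by default; pass a robust covariance from
#' [sandwich_vcov()] for robust inference).
#'
#' @param fit A `"pr_fit"` object.
#' @param term Name of a fitted coefficient.
#' @param cov Covariance matrix of the coefficients; defaults to the
#'   model-based covariance of `fit`.
#' @param level Confidence level.
#' @return An `"effect_estimate"`.
#' @export
extract_effect <- function(fit, term, cov = NULL, level = 0.95) {
  stopifnot(inherits(fit, "pr_fit"))
  if (is.null(cov)) cov <- fit$cov_model
  if (inherits(cov, "robust_vcov")) cov <- cov$matrix
  if (!term %in% names(fit$beta)) stop("no fitted term '", term, "'")
  measure <- if (fit$family == "logistic") "OR" else "PR"
  effect_estimate(measure, exp(unname(fit$beta[term])),
                  sqrt(cov[term, term]), level)
}
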