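#' Inherent bias of the odds ratio relative to the prevalence ratio
#'
#' The OR factorizes as `OR = PR * (1 - p2)/(1 - p1)`; the second factor
#' is the inherent overestimation the OR carries relative to the PR. It
#' approaches 1 when both prevalences are small and grows with the
#' outcome prevalence.
#'
#' @param p1 Outcome prevalence among exposed, in (0, 1).
#' @param p2 Outcome prevalence among unexposed, in (0, 1).
#' @return List with `factor` = (1-p2)/(1-p1) and `pct` = (factor-1)*100.
#' @examples
#' inherent_or_bias(0.4, 0.2)  # factor 4/3, bias ~33.33%
#' @export
inherent_or_bias <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  f <- (1 - p2) / (1 - p1)
  list(factor = f, pct = (f - 1) * 100)
}

#' Precision of a model PR against the Mantel-Haenszel reference
#'
#' `|PR_MH - PR_model| / PR_model * 100` (percent, non-negative).
#'
#' @param pr_mh Mantel-Haenszel (reference) PR.
#' @param pr_model Model PR (> 0).
#' @return Percentage.
#' @examples
#' precision_pr(2.913, 2.931)  # ~0.61
#' @export
precision_pr <- function(pr_mh, pr_model) {
  stopifnot(pr_model > 0)
  abs(pr_mh - pr_model) / pr_model * 100
}

#' Confounding ("confusion") percentage
#'
#' Signed relative change from the crude to the adjusted PR:
#' `(PR_crude - PR_adjusted) / PR_adjusted * 100`. Positive values mean
#' the crude estimate overstates the adjusted association.
#'
#' @param pr_crude Crude PR.
#' @param pr_adjusted Adjusted PR (MH or model-based, > 0).
#' @return Signed percentage.
#' @examples
#' confusion_pct(3.294, 2.913)  # ~13.08
#' @export
confusion_pct <- function(pr_crude, pr_adjusted) {
  stopifnot(pr_adjusted > 0)
  (pr_crude - pr_adjusted) / pr_adjusted * 100
}

#' Precision of a model SE against the Mantel-Haenszel SE
#'
#' `|se_MH - se_model| / se_model * 100` (percent, non-negative), on the
#' log scale of the estimates.
#'
#' @param se_mh Reference (MH) standard error.
#' @param se_model Model standard error (> 0).
#' @return Percentage.
#' @examples
#' se_precision(0.7570, 0.7144)  # ~5.963
#' @export
se_precision <- function(se_mh, se_model) {
  stopifnot(se_model > 0)
  abs(se_mh - se_model) / se_model * 100
}

#' Multi-model comparison report for one outcome
#'
#' Fits every requested regression model with the exposure and the
#' adjustment covariate, with model-based and (optionally) robust
#' variance, alongside the crude 2x2 estimate and - when the adjustment
#' covariate is categorical - the Mantel-Haenszel stratified reference.
#' Each converged PR row carries the confounding percentage against the
#' crude PR and, when an MH reference exists, the SE-precision
#' percentage against the MH standard error. Non-converged models are
#' reported with their status, never dropped.
#'
#' @param data Subject-level data frame.
#' @param outcome,exposure Names of binary 0/1 columns.
#' @param adjust_by Optional name of the adjustment covariate.
#' @param adjust_type `"categorical"` (enables the MH reference row) or
#'   `"numeric"`; MH stratification requires a categorical covariate.
#' @param models Regression families to fit (see [fit_glm()]).
#' @param robust If `TRUE` (default) a robust-variance row is added for
#'   every model.
#' @param level Confidence level.
#' @param scaling Robust finite-sample scaling, see [sandwich_vcov()].
#' @return An object of class `"comparison_report"`: list with
#'   `outcome_label`, `prevalence`, `reference` (`"mh"` or `"crude"`) and
#'   `rows`, a data frame with columns `model`, `variance`, `measure`,
#'   `converged`, `point`, `se_log`, `ci_low`, `ci_high`,
#'   `confusion_pct`, `se_precision_pct`, `bic`.
#' @export
compare_models <- function(data, outcome, exposure, adjust_by = NULL,
                           adjust_type = c("categorical", "numeric"),
                           models = c("negative_log_binomial",
                                      "log_poisson", "log_binomial",
                                      "logistic"),
                           robust = TRUE, level = 0.95,
                           scaling = c("stata", "none")) {
  adjust_type <- match.arg(adjust_type)
  scaling <- match.arg(scaling)
  models <- vapply(models, function(m) match.arg(m, FAMILIES), "")

  crude_tab <- subject_table(data, outcome, exposure)
  crude <- crude_pr(crude_tab, level = level)
  prevalence <- mean(data[[outcome]])

  rows <- list()
  add_row <- function(model, variance, est, converged = "yes",
                      bic_val = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      model = model, variance = variance,
      measure = if (is.null(est)) NA_character_ else est$measure,
      converged = converged,
      point = if (is.null(est)) NA_real_ else est$point,
      se_log = if (is.null(est)) NA_real_ else est$se_log,
      ci_low = if (is.null(est)) NA_real_ else est$ci_low,
      ci_high = if (is.null(est)) NA_real_ else est$ci_high,
      confusion_pct = NA_real_, se_precision_pct = NA_real_,
      bic = bic_val, stringsAsFactors = FALSE)
  }
  add_row("crude", "model", crude)

  mh <- NULL
  if (!is.null(adjust_by) && adjust_type == "categorical") {
    strata <- subject_table(data, outcome, exposure, strata = adjust_by)
    mh <- mh_pr(strata, level = level)
    add_row("mantel_haenszel", "model", mh)
  }

  covariates <- if (is.null(adjust_by)) list() else {
    spec <- list(if (adjust_type == "numeric") "numeric" else "categorical")
    names(spec) <- adjust_by
    spec
  }
  des <- build_design(data, outcome, exposure, covariates)

  for (m in models) {
    fit <- tryCatch(fit_glm(des$y, des$X, m),
                    error = function(e) NULL)
    if (is.null(fit)) { add_row(m, "model", NULL, "error"); next }
    ok <- fit$converged == "yes"
    est <- if (ok) extract_effect(fit, exposure, level = level) else NULL
    add_row(m, "model", est, fit$converged, if (ok) fit$bic else NA_real_)
    if (robust) {
      est_r <- if (ok) effect_with_robust(fit, exposure, level = level,
                                          scaling = scaling) else NULL
      add_row(m, "robust", est_r, fit$converged,
              if (ok) fit$bic else NA_real_)
    }
  }
  rows <- do.call(rbind, rows)
  ref <- if (!is.null(mh) && mh$status == "ok") "mh" else "crude"
  ref_est <- if (ref == "mh") mh else crude
  pr_rows <- which(rows$measure %in% "PR" & !is.na(rows$point) &
                   rows$model != "crude")
  for (i in pr_rows) {
    if (crude$status == "ok")
      rows$confusion_pct[i] <- confusion_pct(crude$point, rows$point[i])
    if (ref == "mh")
      rows$se_precision_pct[i] <- se_precision(ref_est$se_log,
                                               rows$se_log[i])
  }
  structure(list(outcome_label = outcome, prevalence = prevalence,
                 reference = ref, rows = rows),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat(sprintf("outcome '%s' (prevalence %.1f%%), reference: %s\n",
              x$outcome_label, 100 * x$prevalence, x$reference))
  out <- x$rows
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) round(v, digits))
  out$converged[out$converged != "yes"] <-
    ifelse(out$converged[out$converged != "yes"] == "no_boundary",
           "No converge", out$converged[out$converged != "yes"])
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' Numeric cells are written at full precision so that reading the file
#' back recovers every value exactly.
#'
#' @param report A `"comparison_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  rows <- report$rows
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(v) sprintf("%.17g", v))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a comparison report CSV written by [write_report_csv()]
#'
#' @param path File path.
#' @return Data frame with the numeric columns restored.
#' @export
read_report_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("point", "se_log", "ci_low", "ci_high", "confusion_pct",
               "se_precision_pct", "bic"))
    d[[nm]] <- as.numeric(d[[nm]])
  d
}
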