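#' Build a 2x2 contingency table
#'
#' The unit of crude and Mantel-Haenszel estimation. Orientation is fixed
#' throughout the package: rows are exposure (exposed first), columns are
#' outcome (case first), so `a` = exposed cases, `b` = exposed non-cases,
#' `c` = unexposed cases, `d` = unexposed non-cases.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `"tab2x2"` with elements `a`, `b`, `c`, `d`.
#' @examples
#' tab2x2(10, 90, 5, 95)
#' @export
tab2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts))) stop("cell counts must be finite")
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("cell counts must be integers")
  structure(as.list(round(counts)), class = "tab2x2")
}

#' @export
print.tab2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "non-case")))
  print(m)
  invisible(x)
}

#' Group prevalences of a 2x2 table
#'
#' @param table A [tab2x2()] object.
#' @return Named vector with `p1` = a/(a+b) (prevalence among exposed) and
#'   `p2` = c/(c+d) (prevalence among unexposed).
#' @export
prevalences <- function(table) {
  stopifnot(inherits(table, "tab2x2"))
  n1 <- table$a + table$b
  n0 <- table$c + table$d
  if (n1 == 0 || n0 == 0) stop("both exposure margins must be positive")
  c(p1 = table$a / n1, p2 = table$c / n0)
}

#' Bundle stratum-specific 2x2 tables
#'
#' @param tables A list of [tab2x2()] objects, one per stratum.
#' @param labels Unique stratum labels; defaults to names of `tables` or
#'   `"1"`, `"2"`, ...
#' @return An object of class `"stratified_tables"`.
#' @export
stratified_tables <- function(tables, labels = NULL) {
  if (inherits(tables, "tab2x2")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  lapply(tables, function(t) stopifnot(inherits(t, "tab2x2")))
  if (is.null(labels)) labels <- names(tables)
  if (is.null(labels)) labels <- as.character(seq_along(tables))
  if (anyDuplicated(labels)) stop("stratum labels must be unique")
  structure(list(tables = tables, labels = labels),
            class = "stratified_tables")
}

#' @export
print.stratified_tables <- function(x, ...) {
  for (i in seq_along(x$tables)) {
    cat("stratum", x$labels[i], "\n")
    print(x$tables[[i]])
  }
  invisible(x)
}

effect_estimate <- function(measure, point, se_log, level, status = "ok",
                            note = NULL) {
  z <- stats::qnorm((1 + level) / 2)
  if (status == "ok") {
    ci <- wald_ci(point, se_log, level)
    est <- list(measure = measure, point = point, se_log = se_log,
                ci_low = ci[[1]], ci_high = ci[[2]], level = level, z = z,
                status = status, note = note)
  } else {
    est <- list(measure = measure, point = NA_real_, se_log = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, level = level, z = z,
                status = status, note = note)
  }
  structure(est, class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  if (x$status != "ok") {
    cat(sprintf("%s: undefined estimate (%s)\n", x$measure, x$note))
  } else {
    cat(sprintf("%s = %.*f, se(log) = %.*f, %g%% CI (%.*f, %.*f)\n",
                x$measure, digits, x$point, digits, x$se_log,
                100 * x$level, digits, x$ci_low, digits, x$ci_high))
  }
  invisible(x)
}

#' Wald confidence interval on the ratio scale
#'
#' The interval is symmetric on the natural-log scale:
#' `point * exp(-z * se_log)` to `point * exp(+z * se_log)` with
#' `z = qnorm((1 + level) / 2)` (1.959964... for 95%, not the rounded 1.96).
#'
#' @param point Ratio estimate (> 0).
#' @param se_log Standard error of the log estimate (>= 0).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @examples
#' wald_ci(3.294, 0.7126)  # lower limit prints as 0.815
#' @export
wald_ci <- function(point, se_log, level = 0.95) {
  stopifnot(point > 0, se_log >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(ci_low = point * exp(-z * se_log), ci_high = point * exp(z * se_log))
}

#' Crude prevalence ratio from a 2x2 table
#'
#' PR = p1/p2 with the delta-method standard error of ln PR,
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. A zero case count in either
#' exposure group makes the estimate (or its SE) undefined; this is reported
#' as an explicit status, never as a silent infinity.
#'
#' @param table A [tab2x2()] object.
#' @param level Confidence level.
#' @param continuity If `TRUE`, add 0.5 to every cell before estimation
#'   (off by default; no correction is applied unless asked for).
#' @return An `"effect_estimate"` with `measure = "PR"`.
#' @examples
#' crude_pr(tab2x2(10, 90, 5, 95))  # PR = 2
#' @export
crude_pr <- function(table, level = 0.95, continuity = FALSE) {
  stopifnot(inherits(table, "tab2x2"))
  k <- if (continuity) 0.5 else 0
  a <- table$a + k; b <- table$b + k; c <- table$c + k; d <- table$d + k
  if (a + b <= 0 || c + d <= 0)
    stop("both exposure margins must be positive")
  if (c == 0)
    return(effect_estimate("PR", NA, NA, level, status = "undefined",
                           note = "zero unexposed cases (cell c)"))
  if (a == 0)
    return(effect_estimate("PR", NA, NA, level, status = "undefined",
                           note = "zero exposed cases (cell a)"))
  point <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  effect_estimate("PR", point, se, level)
}

#' Crude odds ratio from a 2x2 table
#'
#' OR = (a d)/(b c) with Woolf's standard error of ln OR,
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. Any zero cell makes the estimate
#' undefined and the offending cell is named in the status note.
#'
#' @inheritParams crude_pr
#' @return An `"effect_estimate"` with `measure = "OR"`.
#' @export
crude_or <- function(table, level = 0.95, continuity = FALSE) {
  stopifnot(inherits(table, "tab2x2"))
  k <- if (continuity) 0.5 else 0
  cells <- c(a = table$a + k, b = table$b + k, c = table$c + k,
             d = table$d + k)
  if (any(cells == 0)) {
    zero <- names(cells)[cells == 0]
    return(effect_estimate("OR", NA, NA, level, status = "undefined",
                           note = paste0("zero cell(s): ",
                                         paste(zero, collapse = ", "))))
  }
  point <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  effect_estimate("OR", unname(point), unname(se), level)
}

#' Mantel-Haenszel prevalence ratio across strata
#'
#' Pooled PR `sum(a_i n0_i / n_i) / sum(c_i n1_i / n_i)` with the
#' Greenland-Robins (1985) variance of the log estimate:
#' \deqn{\widehat{Var}(\ln PR_{MH}) =
#'   \frac{\sum_i (m_{1i} n_{1i} n_{0i} - a_i c_i n_i)/n_i^2}{R \cdot S}}
#' where \eqn{m_{1i} = a_i + c_i}, \eqn{n_{1i} = a_i + b_i},
#' \eqn{n_{0i} = c_i + d_i}, \eqn{n_i} the stratum total,
#' \eqn{R = \sum_i a_i n_{0i}/n_i} and \eqn{S = \sum_i c_i n_{1i}/n_i}.
#' This is the standard variance used by mainstream epidemiological
#' software for the MH risk/prevalence ratio.
#'
#' @param strata A [stratified_tables()] object (or a single [tab2x2()],
#'   in which case the result equals [crude_pr()] exactly).
#' @param level Confidence level.
#' @return An `"effect_estimate"` with `measure = "PR"`.
#' @export
mh_pr <- function(strata, level = 0.95) {
  if (inherits(strata, "tab2x2")) strata <- stratified_tables(list(strata))
  stopifnot(inherits(strata, "stratified_tables"))
  R <- S <- V <- 0
  for (t in strata$tables) {
    n1 <- t$a + t$b; n0 <- t$c + t$d; n <- n1 + n0
    if (n == 0) next
    m1 <- t$a + t$c
    R <- R + t$a * n0 / n
    S <- S + t$c * n1 / n
    V <- V + (m1 * n1 * n0 - t$a * t$c * n) / n^2
  }
  if (R <= 0 || S <= 0)
    return(effect_estimate("PR", NA, NA, level, status = "undefined",
                           note = "zero Mantel-Haenszel numerator or denominator sum"))
  effect_estimate("PR", R / S, sqrt(V / (R * S)), level)
}

#' Expand a 2x2 table into subject-level rows
#'
#' Produces one row per subject with binary `outcome` and `exposure`
#' columns, preserving the exact counts; the inverse of
#' [subject_table()]. Useful for fitting regression models to aggregated
#' data.
#'
#' @param table A [tab2x2()] object.
#' @return A data frame with columns `outcome` and `exposure` (0/1).
#' @export
expand_subjects <- function(table) {
  stopifnot(inherits(table, "tab2x2"))
  data.frame(
    outcome  = rep(c(1L, 0L, 1L, 0L), c(table$a, table$b, table$c, table$d)),
    exposure = rep(c(1L, 1L, 0L, 0L), c(table$a, table$b, table$c, table$d))
  )
}

#' Collapse subject-level data to a 2x2 table (optionally per stratum)
#'
#' @param data Data frame of subjects.
#' @param outcome,exposure Names of binary 0/1 columns.
#' @param strata Optional name of a categorical column; if given, a
#'   [stratified_tables()] object is returned with one table per level.
#' @return A [tab2x2()] or [stratified_tables()] object.
#' @export
subject_table <- function(data, outcome, exposure, strata = NULL) {
  y <- check_binary(data[[outcome]], outcome)
  x <- check_binary(data[[exposure]], exposure)
  one <- function(idx) {
    tab2x2(sum(y[idx] == 1 & x[idx] == 1), sum(y[idx] == 0 & x[idx] == 1),
           sum(y[idx] == 1 & x[idx] == 0), sum(y[idx] == 0 & x[idx] == 0))
  }
  if (is.null(strata)) return(one(seq_along(y)))
  s <- data[[strata]]
  if (is.null(s)) stop("no column named '", strata, "'")
  lev <- if (is.factor(s)) levels(s) else sort(unique(as.character(s)))
  s <- as.character(s)
  stratified_tables(lapply(lev, function(l) one(which(s == l))), labels = lev)
}

check_binary <- function(v, name) {
  if (is.null(v)) stop("no column named '", name, "'")
  if (anyNA(v)) stop("column '", name, "' contains missing values")
  if (!all(v %in% c(0, 1))) stop("column '", name, "' must be binary 0/1")
  as.integer(v)
}
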