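#' Reconstruct integer 2x2 tables from published summary statistics
#'
#' Exhaustively searches for every integer 2x2 table consistent with the
#' printed summary values of a crude prevalence-ratio analysis: total
#' sample size, outcome prevalence, PR, log-scale SE and (optionally) the
#' odds ratio. A value "matches" when the candidate table's statistic,
#' rounded half-to-even to the printed number of decimals, equals the
#' printed value - published inputs are themselves rounded, so matching is
#' defined at their printed precision.
#'
#' Published crude rows are routinely computed on complete cases only:
#' when the exposure is measured with an instrument, item non-response
#' makes the effective analysis size smaller than the nominal study size.
#' The search therefore also scans effective sizes down to
#' `n * (1 - allow_missing)`; set `allow_missing = 0` to pin the size
#' exactly.
#'
#' @param n Nominal total sample size.
#' @param outcome_prevalence Overall outcome prevalence as a proportion
#'   (printed at `prev_digits` decimals of a percentage).
#' @param pr Printed crude prevalence ratio.
#' @param se_log Printed standard error of ln PR.
#' @param or_hint Optional printed crude odds ratio; when supplied, only
#'   tables whose OR also rounds to it are returned.
#' @param allow_missing Maximum fraction of `n` allowed to be missing
#'   (complete-case analysis), default 0.10.
#' @param prev_digits,pr_digits,se_digits,or_digits Printed decimals of
#'   the percentage prevalence, PR, SE and OR respectively.
#' @return An object of class `"reconstruction"`: a list with `tables`
#'   (data frame of consistent tables, columns `a,b,c,d,n,pr,se_log,or`,
#'   ordered by `(a, b)`), and when empty, `nearest` (the closest misses).
#' @examples
#' r <- reconstruct_table(200, 0.075, 2.0, 0.52915, allow_missing = 0)
#' r$tables  # contains a=10, b=90, c=5, d=95
#' @export
reconstruct_table <- function(n, outcome_prevalence, pr, se_log,
                              or_hint = NULL, allow_missing = 0.10,
                              prev_digits = 1, pr_digits = 3,
                              se_digits = 4, or_digits = 3) {
  stopifnot(n >= 2, outcome_prevalence > 0, outcome_prevalence < 1,
            pr > 0, se_log > 0, allow_missing >= 0, allow_missing < 1)
  if (n * outcome_prevalence < 1)
    stop("n * outcome_prevalence must be at least 1")
  target_pct <- round(100 * outcome_prevalence, prev_digits)
  half_pr <- 0.5 * 10^(-pr_digits)
  n_eff_range <- seq.int(ceiling(n * (1 - allow_missing)), n)

  hits <- list()
  near <- list()  # bounded set of nearest misses among PR-consistent tables

  for (ne in n_eff_range) {
    # case totals whose printed prevalence matches
    m_lo <- max(1, ceiling(ne * (target_pct - 0.5 * 10^(-prev_digits)) / 100))
    m_hi <- min(ne - 1, floor(ne * (target_pct + 0.5 * 10^(-prev_digits)) / 100))
    if (m_lo > m_hi) next
    for (m in m_lo:m_hi) {
      if (m < 2) next  # PR needs at least one case in each exposure group
      if (round(100 * m / ne, prev_digits) != target_pct) next
      a <- 1:(m - 1)
      cc <- m - a
      # pr(n1) = a*(ne-n1)/(cc*n1) is decreasing in n1; invert the
      # rounding band [pr - half, pr + half] to a narrow n1 interval per a
      lo <- pmax(ceiling(a * ne / (cc * (pr + half_pr) + a) - 1), a)
      hi <- pmin(floor(a * ne / (cc * pmax(pr - half_pr, 1e-12) + a) + 1),
                 ne - cc)
      len <- pmax(hi - lo + 1, 0)
      keep_a <- len > 0
      if (!any(keep_a)) next
      a_e <- rep(a[keep_a], len[keep_a])
      cc_e <- m - a_e
      n1 <- sequence(len[keep_a], from = lo[keep_a])
      n0 <- ne - n1
      prv <- (a_e / n1) / (cc_e / n0)
      sev <- sqrt(1 / a_e - 1 / n1 + 1 / cc_e - 1 / n0)
      bs <- n1 - a_e
      ds <- n0 - cc_e
      orv <- ifelse(bs > 0 & ds > 0, (a_e * ds) / (bs * cc_e), NA_real_)
      ok_pr <- round(prv, pr_digits) == round(pr, pr_digits)
      keep <- ok_pr & round(sev, se_digits) == round(se_log, se_digits)
      if (!is.null(or_hint))
        keep <- keep & !is.na(orv) &
          round(orv, or_digits) == round(or_hint, or_digits)
      if (any(keep))
        hits[[length(hits) + 1]] <-
          data.frame(a = a_e[keep], b = bs[keep], c = cc_e[keep],
                     d = ds[keep], n = ne, pr = prv[keep],
                     se_log = sev[keep], or = orv[keep])
      miss <- ok_pr & !keep
      if (any(miss)) {
        score <- abs(sev - se_log) / se_log +
          ifelse(!is.null(or_hint) & !is.na(orv),
                 abs(orv - or_hint) / max(or_hint, 1e-12), 0)
        j <- which(miss)[order(score[miss])[seq_len(min(5, sum(miss)))]]
        near[[length(near) + 1]] <-
          data.frame(a = a_e[j], b = bs[j], c = cc_e[j], d = ds[j],
                     n = ne, pr = prv[j], se_log = sev[j], or = orv[j],
                     score = score[j])
      }
    }
  }
  tables <- if (length(hits)) do.call(rbind, hits) else
    data.frame(a = integer(), b = integer(), c = integer(), d = integer(),
               n = integer(), pr = numeric(), se_log = numeric(),
               or = numeric())
  tables <- tables[order(tables$a, tables$b, tables$n), , drop = FALSE]
  near <- if (length(near)) do.call(rbind, near) else data.frame()
  nr <- nrow(tables)
  rownames(tables) <- NULL
  nearest <- NULL
  if (!nr && nrow(near)) {
    near <- near[order(near$score), , drop = FALSE]
    nearest <- utils::head(near, 5)
    rownames(nearest) <- NULL
  }
  structure(list(tables = tables, nearest = nearest, n = n,
                 outcome_prevalence = outcome_prevalence, pr = pr,
                 se_log = se_log, or_hint = or_hint,
                 allow_missing = allow_missing),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  if (nrow(x$tables)) {
    cat(nrow(x$tables), "consistent table(s):\n")
    print(x$tables)
  } else {
    cat("no consistent table\n")
    if (!is.null(x$nearest)) {
      cat("nearest misses:\n")
      print(x$nearest)
    }
  }
  invisible(x)
}

#' Convert a reconstruction row to a 2x2 table
#'
#' @param x A `"reconstruction"` object.
#' @param i Row index into `x$tables`.
#' @return A [tab2x2()] object.
#' @export
reconstruction_table <- function(x, i = 1) {
  stopifnot(inherits(x, "reconstruction"), nrow(x$tables) >= i)
  r <- x$tables[i, ]
  tab2x2(r$a, r$b, r$c, r$d)
}
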