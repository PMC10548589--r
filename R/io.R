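#' Parse numbers that may use a decimal comma
#'
#' Published tables sometimes print `0,7126` for `0.7126`; readers in
#' this package accept both separators. Thousands separators are not
#' supported.
#'
#' @param v Character or numeric vector.
#' @return Numeric vector.
#' @export
parse_decimal <- function(v) {
  if (is.numeric(v)) return(v)
  v <- trimws(as.character(v))
  v <- sub("^(-?[0-9]+),([0-9]+)$", "\\1.\\2", v)
  as.numeric(v)
}

#' Read aggregated 2x2 tables from CSV
#'
#' Expects columns `a`, `b`, `c`, `d` and optionally `stratum`
#' (orientation: rows = exposure, exposed first; columns = outcome, case
#' first, i.e. `a` = exposed cases). Decimal commas are accepted. One
#' row yields a [tab2x2()]; several rows yield [stratified_tables()]
#' labelled by `stratum` (or row number).
#'
#' @param path CSV file path.
#' @return A [tab2x2()] or [stratified_tables()] object.
#' @export
read_tables_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  names(d) <- tolower(trimws(names(d)))
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(d)))
    stop("CSV must have columns a, b, c, d (optionally stratum)")
  for (nm in need) {
    d[[nm]] <- parse_decimal(d[[nm]])
    if (anyNA(d[[nm]]))
      stop("non-numeric value in column '", nm, "' of ", path)
  }
  tabs <- lapply(seq_len(nrow(d)), function(i)
    tab2x2(d$a[i], d$b[i], d$c[i], d$d[i]))
  if (nrow(d) == 1) return(tabs[[1]])
  labels <- if ("stratum" %in% names(d)) as.character(d$stratum) else
    as.character(seq_len(nrow(d)))
  stratified_tables(tabs, labels = labels)
}

#' Write effect estimates to a tidy CSV
#'
#' One row per estimate with columns `method`, `measure`, `point`,
#' `se_log`, `ci_low`, `ci_high`, `level`, `status`. All numeric output
#' uses decimal points at full precision.
#'
#' @param estimates A named list of `"effect_estimate"` objects (names
#'   become the `method` column), or a single estimate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (inherits(estimates, "effect_estimate"))
    estimates <- list(estimate = estimates)
  rows <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(method = nm, measure = e$measure,
               point = e$point, se_log = e$se_log,
               ci_low = e$ci_low, ci_high = e$ci_high,
               level = e$level, status = e$status)
  }))
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(v) sprintf("%.17g", v))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a fitting run configuration (YAML or JSON)
#'
#' Recognized fields: `outcome`, `exposure`, `covariates` (named list of
#' `"numeric"` / `"categorical"` / lists with `type`, `levels`, `ref`),
#' `family`, `robust` (logical), `scaling`, `level`, `tol`, `max_iter`,
#' `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path,
                                                    simplifyVector = TRUE)
         else stop("config must be .yaml, .yml or .json")
  if (is.null(cfg$outcome) || is.null(cfg$exposure))
    stop("config must declare 'outcome' and 'exposure'")
  cfg
}

#' Serialize a fit to JSON
#'
#' @param fit A `"pr_fit"` object.
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @param robust Optional `"robust_vcov"` whose SEs are included.
#' @return The JSON string, invisibly if written to `path`.
#' @export
fit_to_json <- function(fit, path = NULL, robust = NULL) {
  stopifnot(inherits(fit, "pr_fit"))
  out <- list(family = fit$family_requested,
              resolved_family = fit$family,
              beta = as.list(fit$beta),
              se_model = as.list(sqrt(diag(fit$cov_model))),
              loglik = fit$loglik, bic = fit$bic, alpha = fit$alpha,
              converged = fit$converged, n_obs = fit$n_obs,
              n_params = fit$n_params, iterations = fit$iterations)
  if (!is.null(robust))
    out$se_robust <- as.list(sqrt(diag(robust$matrix)))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
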