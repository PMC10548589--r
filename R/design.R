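#' Build a response vector and design matrix for model fitting
#'
#' Column order is deterministic: intercept, exposure, then covariates in
#' the order given. Categorical covariates are dummy-encoded with the
#' declared reference level dropped; numeric covariates pass through
#' untransformed.
#'
#' @param data Data frame of subjects (no missing values).
#' @param outcome Name of the binary 0/1 outcome column.
#' @param exposure Name of the binary 0/1 exposure column.
#' @param covariates Named list describing adjustment covariates. Each
#'   element is either the string `"numeric"`, or a list with elements
#'   `type = "categorical"`, optional `levels` (declared levels) and
#'   optional `ref` (reference level, default the first declared level).
#'   A bare string element `"categorical"` uses the sorted observed
#'   levels with the first as reference.
#' @return A list with `y` (integer response), `X` (numeric design matrix
#'   with named columns) and `terms` (column names).
#' @examples
#' d <- data.frame(y = c(0, 1, 1), x = c(0, 1, 1), g = c("a", "b", "a"))
#' build_design(d, "y", "x", list(g = "categorical"))
#' @export
build_design <- function(data, outcome, exposure, covariates = list()) {
  y <- check_binary(data[[outcome]], outcome)
  x <- check_binary(data[[exposure]], exposure)
  n <- length(y)
  cols <- list("(Intercept)" = rep(1, n))
  cols[[exposure]] <- as.numeric(x)
  for (nm in names(covariates)) {
    spec <- covariates[[nm]]
    v <- data[[nm]]
    if (is.null(v)) stop("no column named '", nm, "'")
    if (anyNA(v)) stop("column '", nm, "' contains missing values")
    if (identical(spec, "numeric") ||
        (is.list(spec) && identical(spec$type, "numeric"))) {
      if (!is.numeric(v)) stop("column '", nm, "' is not numeric")
      cols[[nm]] <- as.numeric(v)
    } else {
      lev <- NULL; ref <- NULL
      if (is.list(spec)) { lev <- spec$levels; ref <- spec$ref }
      v <- as.character(v)
      if (is.null(lev))
        lev <- if (is.factor(data[[nm]])) levels(data[[nm]]) else
          sort(unique(v))
      unseen <- setdiff(unique(v), lev)
      if (length(unseen))
        stop("column '", nm, "' has level(s) not declared: ",
             paste(unseen, collapse = ", "))
      if (is.null(ref)) ref <- lev[1]
      if (!ref %in% lev) stop("reference level '", ref,
                              "' is not a level of '", nm, "'")
      for (l in setdiff(lev, ref))
        cols[[paste0(nm, ":", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(y = y, X = X, terms = colnames(X))
}
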