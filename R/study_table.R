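#' Construct a study table
#'
#' Bundles one continuous outcome (right-eye logarithmic visual acuity on the
#' Chinese 5-point decimal scale, roughly 4.0--5.3) with an `n x s` matrix of
#' numeric covariate scores (weekly exercise days 0--7, diet, bullying,
#' mental-stress, internet-use or sleep scores).  Rows with any missing value
#' among the selected columns are dropped (complete-case analysis) and the
#' dropped count is retained.
#'
#' Invariants enforced: `n > s + 2` so the full model has residual degrees of
#' freedom; no missing values after complete-case deletion; every covariate
#' column has nonzero sample variance (a constant column is rejected by name).
#'
#' @param data data frame holding outcome and covariates.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names; default all
#'   remaining numeric columns.
#' @param stage_label free-text label (e.g. `"junior"`), carried through
#'   reports.
#' @return An object of class `study_table`: a list with elements `outcome`
#'   (numeric vector), `covariates` (numeric matrix), `names`, `stage_label`,
#'   `n`, `s`, `dropped` (rows removed as incomplete), `centered` (logical)
#'   and, once centered, `centering` (the centering report).
#' @seealso [center_table()], [read_study_csv()]
#' @export
study_table <- function(data, outcome, covariates = NULL, stage_label = "") {
  stopifnot(is.data.frame(data), is.character(outcome), length(outcome) == 1L)
  if (!outcome %in% names(data))
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          outcome)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (outcome %in% covariates)
    stop("outcome column must not appear among the covariates", call. = FALSE)
  if (length(covariates) < 1L)
    stop("at least one covariate is required", call. = FALSE)

  cols <- data[, c(outcome, covariates), drop = FALSE]
  if (!all(vapply(cols, is.numeric, logical(1))))
    stop("outcome and covariates must be numeric", call. = FALSE)
  ok <- stats::complete.cases(cols)
  dropped <- sum(!ok)
  cols <- cols[ok, , drop = FALSE]

  y <- as.numeric(cols[[outcome]])
  X <- as.matrix(cols[, covariates, drop = FALSE])
  storage.mode(X) <- "double"

  tab <- structure(
    list(outcome = y, covariates = X, names = covariates,
         stage_label = stage_label, n = length(y), s = ncol(X),
         dropped = dropped, centered = FALSE, centering = NULL),
    class = "study_table")
  validate_study_table(tab)
  tab
}

validate_study_table <- function(tab) {
  n <- tab$n; s <- tab$s
  if (n <= s + 2L)
    stop("need n > s + 2 for residual degrees of freedom (n = ", n,
         ", s = ", s, ")", call. = FALSE)
  if (anyNA(tab$outcome) || anyNA(tab$covariates))
    stop("missing values remain after complete-case deletion", call. = FALSE)
  v <- apply(tab$covariates, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- tab$names[v <= 0]
    stop("covariate column(s) with zero variance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Center a study table
#'
#' Subtracts the sample mean from the outcome and from every covariate column
#' so that the always-included intercept can be integrated out under a flat
#' prior.  The original column means are kept in the centering report so all
#' user-facing summaries can be expressed on the raw scale.  Centering an
#' already-centered table is a no-op whose report records means of (numerical)
#' zero.
#'
#' @param tab a [study_table()].
#' @return The centered `study_table`; element `centering` is a list with
#'   `outcome_mean`, `covariate_means` (named) and `dropped`.
#' @export
center_table <- function(tab) {
  stopifnot(inherits(tab, "study_table"))
  validate_study_table(tab)
  ybar <- mean(tab$outcome)
  xbar <- colMeans(tab$covariates)
  tab$outcome <- tab$outcome - ybar
  tab$covariates <- sweep(tab$covariates, 2L, xbar, "-")
  tab$centered <- TRUE
  tab$centering <- list(outcome_mean = ybar,
                        covariate_means = stats::setNames(xbar, tab$names),
                        dropped = tab$dropped)
  tab
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table", if (nzchar(x$stage_label)) paste0("[", x$stage_label, "]"),
      "\n  n =", x$n, " covariates =", x$s,
      if (x$dropped > 0) paste0(" (", x$dropped, " incomplete rows dropped)"),
      "\n  columns:", paste(x$names, collapse = ", "),
      "\n  centered:", x$centered, "\n")
  invisible(x)
}

#' @export
as.data.frame.study_table <- function(x, row.names = NULL, optional = FALSE,
                                      outcome_name = "acuity", ...) {
  df <- data.frame(x$outcome, x$covariates)
  names(df) <- c(outcome_name, x$names)
  df
}

#' Read a study table from CSV
#'
#' Expects a header row, UTF-8 encoding and `.` as the decimal separator.
#'
#' @inheritParams study_table
#' @param path CSV file path.
#' @return A [study_table()].
#' @export
read_study_csv <- function(path, outcome, covariates = NULL,
                           stage_label = "") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  study_table(df, outcome = outcome, covariates = covariates,
              stage_label = stage_label)
}

#' Write a study table (or data frame) to CSV
#'
#' Writes the same dialect [read_study_csv()] expects.
#'
#' @param x a `study_table` or data frame.
#' @param path output CSV path.
#' @param outcome_name outcome column name used when `x` is a `study_table`.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(x, path, outcome_name = "acuity") {
  if (inherits(x, "study_table"))
    x <- as.data.frame(x, outcome_name = outcome_name)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
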