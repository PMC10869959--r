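#' Construct a feature table
#'
#' A feature table is the basic cohort container used throughout the
#' package: an \code{n x p} numeric predictor matrix with unique column
#' names plus a binary outcome vector (1 = successful pregnancy,
#' 0 = unsuccessful). Categorical predictors are expected pre-encoded as
#' integers; no factor handling is done here.
#'
#' @param values numeric matrix (or data frame coercible to one), one row
#'   per treatment cycle, one column per predictor. \code{NA}s are allowed
#'   until \code{\link{impute_median}} is applied.
#' @param outcome vector of 0/1 outcomes, length \code{nrow(values)}.
#' @param feature_names optional character vector of column names; taken
#'   from \code{colnames(values)} when omitted.
#' @return An object of class \code{"feature_table"}: a list with elements
#'   \code{values}, \code{outcome}, \code{feature_names}, \code{n}, \code{p}.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("a", "b"))),
#'                     outcome = rep(c(0, 1), 5))
#' ft$p
#' @export
feature_table <- function(values, outcome, feature_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names))
    feature_names <- paste0("x", seq_len(ncol(values)))
  if (length(feature_names) != ncol(values))
    stop("'feature_names' length must equal ncol(values)")
  if (anyDuplicated(feature_names))
    stop("feature names must be unique")
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(values))
    stop("'outcome' length must equal nrow(values)")
  bad <- stats::na.omit(unique(outcome[!outcome %in% c(0, 1)]))
  if (length(bad) || anyNA(outcome))
    stop("outcome must contain only 0/1; offending values: ",
         paste(utils::head(c(bad, if (anyNA(outcome)) NA), 5), collapse = ", "))
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("need n >= 1 rows and p >= 1 predictor columns")
  colnames(values) <- feature_names
  structure(list(values = values, outcome = outcome,
                 feature_names = feature_names,
                 n = nrow(values), p = ncol(values)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d cycles x %d predictors, prevalence %.3f\n",
              x$n, x$p, mean(x$outcome)))
  invisible(x)
}

#' Read a cohort CSV
#'
#' Reads a header + one-row-per-cycle CSV ('.' decimal separator, empty
#' cells or \code{NA} for missing) and splits it into predictors and the
#' named binary outcome column.
#'
#' @param path path to a CSV file.
#' @param outcome_column name of the 0/1 outcome column.
#' @return A \code{\link{feature_table}} with the outcome column removed
#'   from the predictors and row order preserved.
#' @seealso \code{\link{write_cohort}}
#' @export
read_cohort <- function(path, outcome_column = "outcome") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_column %in% names(d))
    stop("outcome column '", outcome_column, "' not present in ", path)
  y <- d[[outcome_column]]
  d[[outcome_column]] <- NULL
  feature_table(as.matrix(d), outcome = y)
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort}}: predictors first, outcome last,
#' RFC-4180-style CSV with a header row.
#'
#' @param t a \code{\link{feature_table}}.
#' @param path output path.
#' @param outcome_column name to give the outcome column.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(t, path, outcome_column = "outcome") {
  stopifnot(inherits(t, "feature_table"))
  if (outcome_column %in% t$feature_names)
    stop("outcome column name collides with a feature name")
  d <- as.data.frame(t$values, check.names = FALSE)
  d[[outcome_column]] <- t$outcome
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Split a cohort into training and test partitions
#'
#' Deterministic (seeded) train/test split. By default the split is
#' stratified by outcome: with a ~32% positive class an unstratified 20%
#' split is noticeably unstable, so each class is sampled separately at
#' the requested fraction.
#'
#' @param t a \code{\link{feature_table}}.
#' @param test_fraction fraction of rows reserved for testing (default 0.2,
#'   i.e. an 80/20 split).
#' @param seed integer seed controlling the split.
#' @param stratified stratify by outcome class? Default \code{TRUE}.
#' @return An object of class \code{"data_split"}: list with integer
#'   vectors \code{train_indices} and \code{test_indices} (1-based,
#'   disjoint, exhaustive) plus the fraction and seed used.
#' @export
split_train_test <- function(t, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(t, "feature_table"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie in (0,1)")
  if (t$n < 5) stop("need at least 5 rows to split")
  idx <- with_seed(seed, {
    if (stratified) {
      test <- integer(0)
      for (cls in sort(unique(t$outcome))) {
        rows <- which(t$outcome == cls)
        k <- round(length(rows) * test_fraction)
        k <- max(1L, min(k, length(rows) - 1L))
        test <- c(test, sample(rows, k))
      }
      sort(test)
    } else {
      k <- max(1L, min(round(t$n * test_fraction), t$n - 1L))
      sort(sample.int(t$n, k))
    }
  })
  train <- setdiff(seq_len(t$n), idx)
  if (stratified &&
      (length(unique(t$outcome[train])) < 2L ||
       length(unique(t$outcome[idx])) < 2L))
    stop("a class is absent from one partition; cohort too small to stratify")
  structure(list(train_indices = train, test_indices = idx,
                 test_fraction = test_fraction, seed = seed,
                 stratified = stratified),
            class = "data_split")
}

#' Subset a feature table by rows
#'
#' @param t a \code{\link{feature_table}}.
#' @param rows integer row indices to keep.
#' @return A \code{\link{feature_table}} restricted to \code{rows}.
#' @export
subset_rows <- function(t, rows) {
  feature_table(t$values[rows, , drop = FALSE], t$outcome[rows],
                t$feature_names)
}

#' Median imputation fitted on the training partition
#'
#' Replaces every \code{NA} in a column by the median of that column's
#' *training* rows, for training and test rows alike — test-set statistics
#' never enter, so the downstream held-out evaluation stays leakage-free.
#'
#' @param t a \code{\link{feature_table}} (may contain \code{NA}s).
#' @param split a \code{\link{split_train_test}} result; when \code{NULL}
#'   all rows are treated as training rows.
#' @return The imputed \code{\link{feature_table}} (no \code{NA}s).
#' @export
impute_median <- function(t, split = NULL) {
  stopifnot(inherits(t, "feature_table"))
  tr <- if (is.null(split)) seq_len(t$n) else split$train_indices
  v <- t$values
  for (j in seq_len(ncol(v))) {
    if (!anyNA(v[, j])) next
    med <- stats::median(v[tr, j], na.rm = TRUE)
    if (is.na(med))
      stop("column '", t$feature_names[j],
           "' has no observed training value to impute from")
    v[is.na(v[, j]), j] <- med
  }
  feature_table(v, t$outcome, t$feature_names)
}

#' Standardize features by training mean and standard deviation
#'
#' Centers and scales every column by its training-partition mean and
#' population (ddof = 0) standard deviation. Columns constant on the
#' training rows map to all zeros. Needed by scale-sensitive selectors
#' such as the L1-penalised linear model.
#'
#' @inheritParams impute_median
#' @return The rescaled \code{\link{feature_table}}.
#' @export
standardize <- function(t, split = NULL) {
  stopifnot(inherits(t, "feature_table"))
  tr <- if (is.null(split)) seq_len(t$n) else split$train_indices
  v <- t$values
  for (j in seq_len(ncol(v))) {
    m <- mean(v[tr, j])
    s <- pop_sd(v[tr, j])
    v[, j] <- if (s > 0) (v[, j] - m) / s else 0
  }
  feature_table(v, t$outcome, t$feature_names)
}

# population (ddof = 0) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# run expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
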