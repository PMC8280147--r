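# CSV I/O, the two missing-data policies (complete-case deletion and mean
# column imputation), and seeded stratified index splitting.

#' Read a labeled dataset from CSV
#'
#' Expects a header row, one record per patient, a 0/1 label column, and
#' numeric feature columns. Empty fields are read as missing. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param label_column name of the outcome column (default `"label"`).
#' @return a [labeled_dataset()].
#' @export
read_dataset <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, na.strings = "", check.names = FALSE)
  if (nrow(df) == 0) stop("empty dataset: ", path)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not present")
  }
  y <- df[[label_column]]
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("label column must contain only 0/1 with no missing entries")
  }
  x <- df[setdiff(names(df), label_column)]
  labeled_dataset(as.matrix(x), y)
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [read_dataset()]: header row, `label` column first, missing
#' cells as empty fields, numbers at 17 significant digits so the round
#' trip reproduces doubles exactly.
#'
#' @param data a `labeled_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  cells <- apply(data$features, 2, fmt)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  tab <- cbind(label = as.character(data$labels), cells)
  colnames(tab) <- c("label", data$feature_names)
  utils::write.table(tab, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop rows with any missing cell
#'
#' The deletion policy: keep only complete cases, preserving row order.
#'
#' @param data a `labeled_dataset`.
#' @return a `labeled_dataset` of the complete rows.
#' @export
complete_case_filter <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  keep <- which(rowSums(is.na(data$features)) == 0)
  if (length(keep) == 0) stop("complete-case filtering removed every row")
  if (length(unique(data$labels[keep])) < 2) {
    stop("complete-case filtering eliminated an outcome class")
  }
  subset_rows(data, keep)
}

#' Mean column imputation
#'
#' Replaces every missing cell with the mean of the observed values in its
#' column. By default the means are computed on the full dataset before any
#' train/test split -- matching a preprocessing-first pipeline, at the cost
#' of leaking test information into training folds; see the vignette.
#'
#' @param data a `labeled_dataset`.
#' @param means optional named vector of per-column means to use instead
#'   (e.g. means computed on a training subset for the leak-free mode).
#' @return a `labeled_dataset` with no missing cells.
#' @export
mean_impute <- function(data, means = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  x <- data$features
  if (is.null(means)) {
    means <- colMeans(x, na.rm = TRUE)
  }
  if (anyNA(means)) stop("a column has no observed values to impute from")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- means[[j]]
  }
  labeled_dataset(x, data$labels,
                  feature_names = data$feature_names,
                  feature_kinds = data$feature_kinds)
}

#' Seeded stratified train/test split
#'
#' Within each outcome class, `round(test_fraction * class size)`
#' (round-half-up) members are assigned to the test set, selected by a
#' seeded uniform shuffle; the remainder trains. The same
#' `(labels, test_fraction, seed)` always produces the identical split.
#'
#' @param labels 0/1 outcome vector.
#' @param test_fraction fraction of each class sent to the test side,
#'   in (0, 1).
#' @param seed integer seed.
#' @return a list of class `split_indices` with integer elements `train`
#'   and `test` (1-based, disjoint, jointly exhaustive).
#' @export
stratified_split <- function(labels, test_fraction, seed) {
  labels <- as.integer(labels)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly in (0, 1)")
  }
  if (min(table(labels)) < 2) {
    stop("each class needs at least 2 members to appear on both sides")
  }
  test <- integer(0)
  with_local_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n_test <- floor(test_fraction * length(idx) + 0.5)  # round half up
      if (n_test == 0 || n_test == length(idx)) {
        stop("class ", cls, " too small to appear in both train and test")
      }
      test <- c(test, idx[sample.int(length(idx), n_test)])
    }
  })
  test <- sort(test)
  structure(
    list(train = setdiff(seq_along(labels), test), test = test),
    class = "split_indices"
  )
}

#' Seeded stratified k-fold assignment
#'
#' Within each class, rows are shuffled under the seed and dealt round-robin
#' to the `k` folds, so per-fold class counts differ by at most one.
#'
#' @param labels 0/1 outcome vector.
#' @param k number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per row.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  stopifnot(k >= 2)
  if (min(table(labels)) < k) {
    stop("each class needs at least k = ", k, " members")
  }
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      perm <- idx[sample.int(length(idx))]
      fold[perm] <- rep_len(seq_len(k), length(perm))
    }
  })
  fold
}
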