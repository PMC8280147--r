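#' Labeled tabular dataset
#'
#' The universal input of the package: an `n x p` numeric feature matrix
#' (missing cells as `NA`), a binary outcome vector, and per-column
#' metadata. Both outcome classes must be present.
#'
#' @param features numeric matrix (or data frame) of predictors; `NA` marks
#'   a missing cell.
#' @param labels vector of 0/1 outcomes, one per row.
#' @param feature_names optional column names; defaults to existing column
#'   names or `x1..xp`.
#' @param feature_kinds optional per-column tags, `"continuous"` or
#'   `"binary"`; inferred from the observed values when omitted.
#' @return an object of class `labeled_dataset`: a list with elements
#'   `features`, `labels`, `feature_names`, `feature_kinds`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL,
                            feature_kinds = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`features` row count must equal `labels` length")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must contain only 0 and 1")
  }
  if (length(unique(labels)) < 2) {
    stop("both outcome classes must be present")
  }
  p <- ncol(features)
  feature_names <- feature_names %||% colnames(features) %||%
    sprintf("x%d", seq_len(p))
  if (is.null(feature_kinds)) {
    feature_kinds <- vapply(seq_len(p), function(j) {
      v <- features[, j]
      v <- v[!is.na(v)]
      if (length(v) > 0 && all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  stopifnot(
    length(feature_names) == p,
    length(feature_kinds) == p,
    all(feature_kinds %in% c("continuous", "binary"))
  )
  colnames(features) <- feature_names
  structure(
    list(
      features = features,
      labels = labels,
      feature_names = feature_names,
      feature_kinds = feature_kinds
    ),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<labeled_dataset> %d rows, %d features (%d continuous, %d binary)\n",
    n, ncol(x$features),
    sum(x$feature_kinds == "continuous"),
    sum(x$feature_kinds == "binary")
  ))
  cat(sprintf(
    "  prevalence: %.3f; missing cells: %d\n",
    mean(x$labels), sum(is.na(x$features))
  ))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

#' Subset the rows of a labeled dataset
#'
#' Row subsetting that keeps features and labels aligned. Errors if the
#' subset eliminates an outcome class.
#'
#' @param data a `labeled_dataset`.
#' @param rows integer row indices (1-based).
#' @return a `labeled_dataset`.
#' @export
subset_rows <- function(data, rows) {
  stopifnot(inherits(data, "labeled_dataset"))
  labeled_dataset(
    data$features[rows, , drop = FALSE],
    data$labels[rows],
    feature_names = data$feature_names,
    feature_kinds = data$feature_kinds
  )
}
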