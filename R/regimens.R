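# The six validation regimens. Each takes (dataset, classifier, seed),
# derives every random draw from the seed alone (so splits are identical
# across classifiers given the same seed), and returns a regimen_result
# holding the pooled predictions and the AUC. Cross-validation AUCs are
# "global": predictions are concatenated across folds and a single AUC is
# computed, rather than averaging per-fold AUCs. The bootstrap instead
# averages per-replicate out-of-bag AUCs, with the pooled concatenation
# retained for its DeLong interval.

new_regimen_result <- function(regimen, seed, pooled, pooled_indices,
                               auc_aggregation = "pooled",
                               per_rep_aucs = numeric(0),
                               n_train = NA_integer_, n_test = NA_integer_,
                               auc_value = NULL, extra = list()) {
  structure(
    c(list(
      regimen = regimen, seed = seed, pooled = pooled,
      pooled_indices = pooled_indices,
      auc_value = auc_value %||% auc(pooled),
      auc_aggregation = auc_aggregation,
      per_rep_aucs = per_rep_aucs,
      n_train = n_train, n_test = n_test
    ), extra),
    class = "regimen_result"
  )
}

#' @export
print.regimen_result <- function(x, ...) {
  cat(sprintf("<regimen_result: %s> seed=%s AUC=%.4f (%s), pooled m=%d\n",
              x$regimen, format(x$seed), x$auc_value, x$auc_aggregation,
              length(x$pooled$y_true)))
  invisible(x)
}

fit_and_score <- function(clf, data, train_idx, test_idx) {
  state <- clf$fit(data$features[train_idx, , drop = FALSE],
                   data$labels[train_idx])
  clf$predict_score(state, data$features[test_idx, , drop = FALSE])
}

#' Stratified split-sample (hold-out) validation
#'
#' One stratified train/test partition from the seed; the model is fit on
#' the training side and the AUC computed on the test-side predictions
#' only.
#'
#' @param data a `labeled_dataset` with no missing cells.
#' @param model a classifier (see [make_classifier()]).
#' @param test_fraction fraction of each class held out (0.5 and 0.3 are
#'   the conventional 50/50 and 70/30 regimens).
#' @param seed integer split seed.
#' @return a `regimen_result`.
#' @export
split_validate <- function(data, model, test_fraction, seed) {
  stopifnot(inherits(data, "labeled_dataset"))
  idx <- stratified_split(data$labels, test_fraction, seed)
  scores <- fit_and_score(model, data, idx$train, idx$test)
  pooled <- scored_predictions(data$labels[idx$test], scores)
  new_regimen_result(
    regimen = if (isTRUE(all.equal(test_fraction, 0.5))) "split5050"
              else if (isTRUE(all.equal(test_fraction, 0.3))) "split7030"
              else sprintf("split_%g", test_fraction),
    seed = seed, pooled = pooled, pooled_indices = idx$test,
    n_train = length(idx$train), n_test = length(idx$test)
  )
}

#' Stratified k-fold cross-validation with pooled predictions
#'
#' Partitions the rows into `k` stratified folds from the seed; each fold
#' is scored by a model fit on the other `k - 1`. Predictions are
#' concatenated across folds (each sample appears exactly once) and a
#' single global AUC is computed from the concatenation.
#'
#' @inheritParams split_validate
#' @param k number of folds (default 10).
#' @return a `regimen_result`; `per_rep_aucs` holds the per-fold AUCs for
#'   reference (they are not used for `auc_value`).
#' @export
kfold_cv <- function(data, model, k = 10L, seed = 0L) {
  stopifnot(inherits(data, "labeled_dataset"))
  fold <- stratified_folds(data$labels, k, seed)
  all_idx <- integer(0)
  all_scores <- numeric(0)
  fold_aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    scores <- fit_and_score(model, data, train_idx, test_idx)
    all_idx <- c(all_idx, test_idx)
    all_scores <- c(all_scores, scores)
    yt <- data$labels[test_idx]
    if (length(unique(yt)) == 2) {
      fold_aucs[f] <- auc(scored_predictions(yt, scores))
    }
  }
  pooled <- scored_predictions(data$labels[all_idx], all_scores)
  new_regimen_result(
    regimen = sprintf("kfold%d", k), seed = seed, pooled = pooled,
    pooled_indices = all_idx, per_rep_aucs = fold_aucs,
    n_train = length(data$labels) - tabulate(fold, k),
    n_test = tabulate(fold, k)
  )
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs [kfold_cv()] `repeats` times under sub-seeds derived
#' deterministically from `seed` ([derive_seed()]; repeat 0 uses `seed`
#' itself, so `repeats = 1` reduces exactly to [kfold_cv()]). Predictions
#' from all `repeats * k` folds are concatenated -- each sample appears
#' exactly `repeats` times -- and one global AUC is computed.
#'
#' @inheritParams kfold_cv
#' @param repeats number of k-fold repetitions (default 10).
#' @return a `regimen_result`; `per_rep_aucs` holds each repeat's pooled
#'   AUC.
#' @export
repeated_kfold <- function(data, model, k = 10L, repeats = 10L, seed = 0L) {
  stopifnot(repeats >= 1)
  runs <- lapply(seq_len(repeats) - 1L, function(r) {
    kfold_cv(data, model, k = k, seed = derive_seed(seed, r))
  })
  pooled <- scored_predictions(
    unlist(lapply(runs, function(r) r$pooled$y_true)),
    unlist(lapply(runs, function(r) r$pooled$scores))
  )
  new_regimen_result(
    regimen = sprintf("repeated%dx%d", repeats, k), seed = seed,
    pooled = pooled,
    pooled_indices = unlist(lapply(runs, function(r) r$pooled_indices)),
    per_rep_aucs = vapply(runs, function(r) r$auc_value, numeric(1)),
    n_train = length(data$labels) - length(data$labels) %/% k,
    n_test = length(data$labels) %/% k
  )
}

#' Out-of-bag bootstrap validation
#'
#' Per replicate: a training multiset of size `n` is drawn with
#' replacement (from a sub-seed of `seed`), the model is fit on it and
#' scored on the out-of-bag rows (those never drawn; about `1 - 1/e` = 36.8%
#' of the data for large `n`). The regimen's AUC is the mean of the
#' per-replicate out-of-bag AUCs; the concatenation of all replicates' OOB
#' predictions is retained, as the DeLong interval is conventionally
#' computed from it (note these pooled predictions are statistically
#' dependent across replicates -- the mean AUC can fall outside the
#' interval). Replicates whose OOB set (or training multiset) lacks a class
#' are redrawn within the same sub-stream; the count is recorded as
#' `n_redraws`.
#'
#' @inheritParams split_validate
#' @param n_reps number of bootstrap replicates (default 500).
#' @return a `regimen_result` with `auc_aggregation = "mean_of_reps"` and
#'   extra fields `n_redraws`, `oob_fractions` and `train_sizes`.
#' @export
bootstrap_validate <- function(data, model, n_reps = 500L, seed = 0L) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$labels)
  if (n < 10) stop("bootstrap validation needs n >= 10")
  per_rep_aucs <- numeric(n_reps)
  oob_fracs <- numeric(n_reps)
  train_sizes <- integer(n_reps)
  all_y <- vector("list", n_reps)
  all_s <- vector("list", n_reps)
  all_i <- vector("list", n_reps)
  n_redraws <- 0L
  for (r in seq_len(n_reps)) {
    draw <- with_local_seed(derive_seed(seed, r), {
      repeat {
        train_idx <- sample.int(n, n, replace = TRUE)
        oob <- which(!(seq_len(n) %in% train_idx))
        ok <- length(unique(data$labels[oob])) == 2 &&
          length(unique(data$labels[train_idx])) == 2
        if (ok) break
        n_redraws <- n_redraws + 1L  # promise evaluates in this frame
        if (n_redraws > 100L * n_reps) stop("all bootstrap replicates degenerate")
      }
      list(train_idx = train_idx, oob = oob)
    })
    scores <- fit_and_score(model, data, draw$train_idx, draw$oob)
    preds <- scored_predictions(data$labels[draw$oob], scores)
    per_rep_aucs[r] <- auc(preds)
    oob_fracs[r] <- length(draw$oob) / n
    train_sizes[r] <- length(draw$train_idx)
    all_y[[r]] <- preds$y_true
    all_s[[r]] <- preds$scores
    all_i[[r]] <- draw$oob
  }
  pooled <- scored_predictions(unlist(all_y), unlist(all_s))
  new_regimen_result(
    regimen = sprintf("bootstrap%d", n_reps), seed = seed, pooled = pooled,
    pooled_indices = unlist(all_i),
    auc_aggregation = "mean_of_reps", per_rep_aucs = per_rep_aucs,
    n_train = n, n_test = round(mean(oob_fracs) * n),
    auc_value = mean(per_rep_aucs),
    extra = list(n_redraws = n_redraws, oob_fractions = oob_fracs,
                 train_sizes = train_sizes)
  )
}

#' Leave-one-out validation
#'
#' For each row `i`, the model is fit on the other `n - 1` rows and scores
#' row `i`; the `n` held-out predictions are pooled into one AUC. There is
#' no seed: LOO has no split stochasticity, so repeated invocations are
#' identical.
#'
#' @inheritParams split_validate
#' @return a `regimen_result` with `seed = NA`.
#' @export
loo_validate <- function(data, model) {
  stopifnot(inherits(data, "labeled_dataset"))
  n <- length(data$labels)
  if (n < 3) stop("leave-one-out needs n >= 3")
  if (min(table(data$labels)) < 2) {
    stop("each class needs >= 2 members so every training set keeps both")
  }
  scores <- vapply(seq_len(n), function(i) {
    fit_and_score(model, data, setdiff(seq_len(n), i), i)
  }, numeric(1))
  pooled <- scored_predictions(data$labels, scores)
  new_regimen_result(
    regimen = "loo", seed = NA_integer_, pooled = pooled,
    pooled_indices = seq_len(n), n_train = n - 1L, n_test = 1L
  )
}

#' Run a regimen by tag
#'
#' Dispatch helper used by the stability harness and the pipeline.
#' Recognized tags: `split5050`, `split7030`, `kfold10` (any `kfoldK`),
#' `repeated10x10` (any `repeatedRxK`), `bootstrap500` (any `bootstrapN`),
#' `loo`.
#'
#' @param data a `labeled_dataset`.
#' @param model a classifier.
#' @param regimen regimen tag.
#' @param seed integer seed (ignored for `loo`).
#' @return a `regimen_result`.
#' @export
run_regimen <- function(data, model, regimen, seed = 0L) {
  if (regimen == "loo") return(loo_validate(data, model))
  m <- regmatches(regimen, regexec("^split(\\d{2})(\\d{2})$", regimen))[[1]]
  if (length(m)) {
    return(split_validate(data, model,
                          test_fraction = as.numeric(m[3]) / 100, seed = seed))
  }
  m <- regmatches(regimen, regexec("^kfold(\\d+)$", regimen))[[1]]
  if (length(m)) {
    return(kfold_cv(data, model, k = as.integer(m[2]), seed = seed))
  }
  m <- regmatches(regimen, regexec("^repeated(\\d+)x(\\d+)$", regimen))[[1]]
  if (length(m)) {
    return(repeated_kfold(data, model, k = as.integer(m[3]),
                          repeats = as.integer(m[2]), seed = seed))
  }
  m <- regmatches(regimen, regexec("^bootstrap(\\d+)$", regimen))[[1]]
  if (length(m)) {
    return(bootstrap_validate(data, model, n_reps = as.integer(m[2]),
                              seed = seed))
  }
  stop("unknown regimen tag: '", regimen, "'")
}
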