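# The four reference classifiers behind the classifier contract, plus
# mutual-information feature ranking. A classifier is a list with `name`,
# `internal_seed`, `fit(x, y) -> state` and `predict_score(state, x) ->
# class-1 probabilities`. Logistic regression, Gaussian naive Bayes and LDA
# are deterministic; the random forest consumes `internal_seed`, held fixed
# across validation seeds so split variation is the only stochastic input.

new_classifier <- function(name, fit, predict_score, internal_seed = NULL,
                           hyperparameters = list()) {
  structure(
    list(name = name, fit = fit, predict_score = predict_score,
         internal_seed = internal_seed, hyperparameters = hyperparameters),
    class = "vs_classifier"
  )
}

#' @export
print.vs_classifier <- function(x, ...) {
  cat(sprintf("<classifier: %s>", x$name))
  if (!is.null(x$internal_seed)) {
    cat(sprintf(" internal_seed=%d", x$internal_seed))
  }
  cat("\n")
  invisible(x)
}

#' Construct one of the four reference classifiers
#'
#' @param name one of `"logistic"`, `"gnb"`, `"lda"`, `"random_forest"`.
#' @param internal_seed seed for the random forest's internal randomness
#'   (tree bootstraps and per-node feature draws); ignored by the three
#'   deterministic models. Held fixed across validation seeds.
#' @param ... hyperparameter overrides. The random forest accepts `n_trees`
#'   (default 100), `mtry` (default `floor(sqrt(p))`) and `min_split`
#'   (default 2, i.e. trees grown to purity). The Gaussian naive Bayes
#'   accepts `var_floor_frac` (default 1e-9): the per-class variance floor
#'   as a fraction of the largest overall feature variance.
#' @return a classifier object satisfying the contract above. All models
#'   emit class-1 probabilities in `[0, 1]`.
#' @details
#' Logistic regression is an unpenalized GLM fit (IRLS); rank-deficient
#' columns get zero coefficients. LDA delegates to [MASS::lda()], with
#' columns of (near) zero pooled within-class variance dropped before the
#' fit. The Gaussian naive Bayes is implemented natively: per-class,
#' per-feature Gaussian likelihoods with maximum-likelihood variances and
#' class priors from training frequencies. The random forest is a native
#' implementation (compiled): per-tree bootstrap of the training rows, Gini
#' impurity splits over `mtry` features drawn per node, trees grown to
#' purity, predicted probability = mean over trees of the leaf class-1
#' fraction.
#' @export
make_classifier <- function(name, internal_seed = 0L, ...) {
  opts <- list(...)
  switch(
    name,
    logistic = classifier_logistic(),
    gnb = classifier_gnb(var_floor_frac = opts$var_floor_frac %||% 1e-9),
    lda = classifier_lda(),
    random_forest = classifier_rf(
      internal_seed = internal_seed,
      n_trees = opts$n_trees %||% 100L,
      mtry = opts$mtry %||% NA_integer_,
      min_split = opts$min_split %||% 2L
    ),
    stop("unknown classifier name: '", name, "'")
  )
}

#' The paper-default classifier battery
#'
#' @param internal_seed internal seed handed to the random forest.
#' @return list of the four classifiers (logistic, gnb, lda, random_forest).
#' @export
default_classifiers <- function(internal_seed = 0L) {
  lapply(c("logistic", "gnb", "lda", "random_forest"),
         make_classifier, internal_seed = internal_seed)
}

classifier_logistic <- function() {
  new_classifier(
    name = "logistic",
    fit = function(x, y) {
      xd <- cbind(`(Intercept)` = 1, x)
      fit <- suppressWarnings(
        glm.fit(xd, y, family = binomial(), control = list(maxit = 50))
      )
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0      # rank-deficient columns contribute 0
      list(coefficients = coefs)
    },
    predict_score = function(state, x) {
      plogis(drop(cbind(1, x) %*% state$coefficients))
    },
    hyperparameters = list(penalty = "none", maxit = 50)
  )
}

classifier_gnb <- function(var_floor_frac = 1e-9) {
  new_classifier(
    name = "gnb",
    fit = function(x, y) {
      classes <- c(0L, 1L)
      overall_var <- apply(x, 2, function(v) mean((v - mean(v))^2))
      floor_v <- max(var_floor_frac * max(overall_var, 0), 1e-300)
      stats_by_class <- lapply(classes, function(cls) {
        xi <- x[y == cls, , drop = FALSE]
        mu <- colMeans(xi)
        # maximum-likelihood (1/n) variances, floored to keep the density
        # finite on within-class-constant features
        v <- colMeans(sweep(xi, 2, mu)^2)
        list(mu = mu, var = pmax(v, floor_v), prior = nrow(xi) / nrow(x))
      })
      names(stats_by_class) <- as.character(classes)
      stats_by_class
    },
    predict_score = function(state, x) {
      loglik <- function(s) {
        centered2 <- sweep(x, 2, s$mu)^2
        rowSums(sweep(centered2, 2, -1 / (2 * s$var), "*")) -
          sum(0.5 * log(2 * pi * s$var)) + log(s$prior)
      }
      l0 <- loglik(state[["0"]])
      l1 <- loglik(state[["1"]])
      1 / (1 + exp(l0 - l1))
    },
    hyperparameters = list(var_floor_frac = var_floor_frac)
  )
}

classifier_lda <- function() {
  new_classifier(
    name = "lda",
    fit = function(x, y) {
      # MASS::lda rejects variables that are constant within groups; drop
      # columns whose pooled within-class variance is (numerically) zero
      pooled_var <- (apply(x[y == 0, , drop = FALSE], 2, var) +
                       apply(x[y == 1, , drop = FALSE], 2, var)) / 2
      keep <- which(pooled_var > 1e-10 & is.finite(pooled_var))
      if (length(keep) == 0) stop("no usable features for LDA")
      fit <- suppressWarnings(
        MASS::lda(x[, keep, drop = FALSE], grouping = factor(y, c(0, 1)))
      )
      list(fit = fit, keep = keep)
    },
    predict_score = function(state, x) {
      post <- predict(state$fit, x[, state$keep, drop = FALSE])$posterior
      unname(post[, "1"])
    },
    hyperparameters = list(engine = "MASS::lda", prior = "proportions")
  )
}

classifier_rf <- function(internal_seed, n_trees, mtry, min_split) {
  new_classifier(
    name = "random_forest",
    internal_seed = as.integer(internal_seed),
    fit = function(x, y) {
      m <- if (is.na(mtry)) max(1L, floor(sqrt(ncol(x)))) else as.integer(mtry)
      list(forest = rf_fit(x, as.integer(y), as.integer(n_trees), m,
                           as.integer(min_split), as.integer(internal_seed)))
    },
    predict_score = function(state, x) {
      drop(rf_predict(state$forest, x))
    },
    hyperparameters = list(n_trees = n_trees, mtry = mtry,
                           min_split = min_split, criterion = "gini")
  )
}

#' Wrap a fixed scoring function as a classifier
#'
#' The returned object satisfies the classifier contract but ignores the
#' training data entirely: `score_fun(x)` is applied to the feature matrix
#' as-is. Useful for testing pooling identities (a fit-free scorer must
#' give the same AUC whether predictions are pooled across folds or
#' computed on the full dataset) and as a null model.
#'
#' @param score_fun function from a feature matrix to a numeric vector.
#' @param name label for reports.
#' @return a classifier object.
#' @export
fixed_scorer <- function(score_fun, name = "fixed_scorer") {
  new_classifier(
    name = name,
    fit = function(x, y) list(),
    predict_score = function(state, x) as.numeric(score_fun(x)),
    hyperparameters = list(fit_free = TRUE)
  )
}

fit_classifier <- function(clf, x, y) clf$fit(x, y)
score_classifier <- function(clf, state, x) clf$predict_score(state, x)

# ---------------------------------------------------------------------------

#' Mutual-information feature ranking
#'
#' Per-feature mutual information (in nats) with the binary label. Binary
#' features use the exact plug-in discrete MI. Continuous features are
#' discretized into `q` equal-frequency bins (rank-based, so the score is
#' invariant under strictly monotone transforms) and then plug-in MI is
#' computed. A constant feature has MI 0. Ties in the ranking are broken by
#' ascending feature index.
#'
#' @param data a `labeled_dataset` with no missing cells.
#' @param m number of features to select.
#' @param q number of equal-frequency bins for continuous features
#'   (default 10).
#' @return object of class `feature_ranking`: list with `scores`
#'   (per-feature MI, nats), `order` (feature indices, descending score)
#'   and `selected` (the top `m`).
#' @export
mutual_information_rank <- function(data, m, q = 10L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (anyNA(data$features)) stop("impute or filter missing cells first")
  p <- ncol(data$features)
  stopifnot(m >= 1, m <= p)
  y <- data$labels
  scores <- vapply(seq_len(p), function(j) {
    v <- data$features[, j]
    if (data$feature_kinds[j] == "binary") {
      plugin_mi(as.integer(v), y)
    } else {
      plugin_mi(equal_frequency_bins(v, q), y)
    }
  }, numeric(1))
  ord <- order(-scores, seq_len(p))
  structure(
    list(scores = scores, order = ord, selected = ord[seq_len(m)],
         feature_names = data$feature_names),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking> top features (MI, nats):\n")
  for (j in x$selected) {
    cat(sprintf("  %-16s %.4f\n", x$feature_names[j], x$scores[j]))
  }
  invisible(x)
}

# Rank-based equal-frequency binning; monotone-transform invariant,
# deterministic (ties broken by position).
equal_frequency_bins <- function(v, q) {
  n <- length(v)
  r <- rank(v, ties.method = "first")
  as.integer(ceiling(r * min(q, n) / n))
}

# Plug-in discrete MI in nats: sum p_ij log(p_ij / (p_i. p_.j)).
plugin_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}
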