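# ROC inference: Mann-Whitney AUC with midrank tie handling, the empirical
# ROC curve, DeLong structural-components variance and Wald confidence
# intervals, Hanley-McNeil closed-form standard errors, the non-directional
# z-test between two independent ROC curves, and thresholded accuracy/F1.

#' Paired true labels and predicted scores
#'
#' The unit on which all ROC statistics operate. Scores are any real
#' ordering (probabilities for the bundled classifiers); both classes must
#' be present.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores, same length.
#' @return object of class `scored_predictions` with elements `y_true`,
#'   `scores`, `n1` (positives), `n0` (negatives).
#' @export
scored_predictions <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  scores <- as.numeric(scores)
  if (length(y_true) != length(scores)) {
    stop("`y_true` and `scores` must have equal length")
  }
  if (!all(y_true %in% c(0L, 1L))) stop("`y_true` must be 0/1")
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 < 1 || n0 < 1) stop("both classes must be present")
  if (anyNA(scores)) stop("`scores` must be finite")
  structure(list(y_true = y_true, scores = scores, n1 = n1, n0 = n0),
            class = "scored_predictions")
}

as_preds <- function(x) {
  if (inherits(x, "scored_predictions")) x else
    stop("expected a `scored_predictions` object")
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive is scored above a random negative,
#' with tied scores counting one half: over all `n1 * n0` positive/negative
#' pairs, concordant pairs count 1 and ties 1/2. Computed via midranks in
#' `O(m log m)`; identical to the trapezoidal area under [roc_curve()].
#'
#' @param preds a [scored_predictions()].
#' @return the AUC, in `[0, 1]`.
#' @export
auc <- function(preds) {
  p <- as_preds(preds)
  r <- rank(p$scores, ties.method = "average")
  (sum(r[p$y_true == 1L]) - p$n1 * (p$n1 + 1) / 2) / (p$n1 * p$n0)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order, classifying `score >= threshold` as positive. Returns the
#' operating points `(FPR, TPR)` with `FPR = FP / (TN + FP)` and
#' `TPR = TP / (TP + FN)`, starting at (0, 0) and ending at (1, 1). The
#' trapezoidal area under the returned curve equals [auc()].
#'
#' @param preds a [scored_predictions()].
#' @return data frame with columns `threshold` (`Inf` for the (0, 0)
#'   point), `fpr`, `tpr`.
#' @export
roc_curve <- function(preds) {
  p <- as_preds(preds)
  ord <- order(p$scores, decreasing = TRUE)
  y <- p$y_true[ord]
  s <- p$scores[ord]
  last <- which(diff(s) != 0)          # last index of each distinct score
  last <- c(last, length(s))
  tp <- cumsum(y)[last]
  fp <- last - tp
  data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / p$n0),
    tpr = c(0, tp / p$n1)
  )
}

# Per-observation structural components. V10[i]: mean over negatives of
# psi(x_i, y_j); V01[j]: mean over positives; psi = 1 / 0.5 / 0 for
# greater / tied / lesser. Midrank identities give them in O(m log m).
delong_components <- function(p) {
  pos <- p$scores[p$y_true == 1L]
  neg <- p$scores[p$y_true == 0L]
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  n1 <- p$n1
  n0 <- p$n0
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01)
}

#' DeLong variance of the AUC
#'
#' Nonparametric structural-components estimator:
#' `var = S10 / n1 + S01 / n0`, where `S10` and `S01` are the sample
#' variances (n - 1 denominator) of the per-positive and per-negative
#' components. Ties use the midrank convention throughout.
#'
#' @param preds a [scored_predictions()] with at least 2 members per class.
#' @return nonnegative variance estimate.
#' @export
delong_variance <- function(preds) {
  p <- as_preds(preds)
  if (p$n1 < 2 || p$n0 < 2) {
    stop("DeLong variance needs at least 2 members in each class")
  }
  cmp <- delong_components(p)
  var(cmp$v10) / p$n1 + var(cmp$v01) / p$n0
}

#' DeLong confidence interval for the AUC
#'
#' Wald interval `auc +/- z * sqrt(var)` on the plain AUC scale, clipped to
#' `[0, 1]`; no logit transform.
#'
#' @param preds a [scored_predictions()].
#' @param level confidence level (default 0.95).
#' @return object of class `auc_estimate`: list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `level`, `n1`, `n0`.
#' @export
delong_ci <- function(preds, level = 0.95) {
  p <- as_preds(preds)
  a <- auc(p)
  v <- delong_variance(p)
  z <- qnorm((1 + level) / 2)
  half <- z * sqrt(v)
  structure(
    list(
      auc = a, variance = v,
      ci_low = max(0, a - half), ci_high = min(1, a + half),
      level = level, n1 = p$n1, n0 = p$n0
    ),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f, %d%% CI [%.3f-%.3f] (DeLong), n1=%d n0=%d\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high, x$n1, x$n0))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form SE from the AUC value and the class sizes alone:
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)) / (n1 n0)` with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`. This is the SE behind the
#' classical independent two-ROC z-test.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @param n1,n0 positive and negative class sizes (>= 1).
#' @return nonnegative standard error.
#' @export
hanley_mcneil_se <- function(auc_value, n1, n0) {
  stopifnot(auc_value >= 0, auc_value <= 1, n1 >= 1, n0 >= 1)
  a <- auc_value
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
    (n1 * n0)
  sqrt(max(v, 0))
}

#' Non-directional test between two independent ROC curves
#'
#' Unpaired z-test `z = (A_a - A_b) / sqrt(SE_a^2 + SE_b^2)` with two-sided
#' p-value `2 (1 - Phi(|z|))`. Standard errors are Hanley-McNeil by default
#' (the classical independent comparison) or DeLong. The samples are
#' treated as independent; no pairing structure is used or assumed.
#'
#' @param preds_a,preds_b two [scored_predictions()] objects.
#' @param method `"hanley_mcneil"` (default) or `"delong"`.
#' @return object of class `roc_comparison`: list with `auc_a`, `auc_b`,
#'   `se_a`, `se_b`, `z`, `p_two_sided`, `method`.
#' @export
independent_roc_test <- function(preds_a, preds_b,
                                 method = c("hanley_mcneil", "delong")) {
  method <- match.arg(method)
  a <- as_preds(preds_a)
  b <- as_preds(preds_b)
  auc_a <- auc(a)
  auc_b <- auc(b)
  se <- function(p, a_val) {
    if (method == "hanley_mcneil") hanley_mcneil_se(a_val, p$n1, p$n0)
    else sqrt(delong_variance(p))
  }
  se_a <- se(a, auc_a)
  se_b <- se(b, auc_b)
  pooled <- sqrt(se_a^2 + se_b^2)
  if (pooled == 0) {
    z <- if (auc_a == auc_b) 0 else Inf * sign(auc_a - auc_b)
  } else {
    z <- (auc_a - auc_b) / pooled
  }
  structure(
    list(
      auc_a = auc_a, auc_b = auc_b, se_a = se_a, se_b = se_b,
      z = z, p_two_sided = 2 * (1 - pnorm(abs(z))), method = method
    ),
    class = "roc_comparison"
  )
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "independent ROC comparison (%s): A=%.3f vs %.3f, z=%.3f, p=%.4g\n",
    x$method, x$auc_a, x$auc_b, x$z, x$p_two_sided))
  invisible(x)
}

#' Thresholded accuracy and F1
#'
#' Classifies `score >= threshold` as positive. `accuracy = (TP + TN) / m`;
#' `F1 = 2 TP / (2 TP + FP + FN)` (0 when no true positive is predicted).
#'
#' @param preds a [scored_predictions()].
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector `c(accuracy, f1)`.
#' @export
accuracy_f1 <- function(preds, threshold = 0.5) {
  p <- as_preds(preds)
  pred <- as.integer(p$scores >= threshold)
  tp <- sum(pred == 1L & p$y_true == 1L)
  tn <- sum(pred == 0L & p$y_true == 0L)
  fp <- sum(pred == 1L & p$y_true == 0L)
  fn <- sum(pred == 0L & p$y_true == 1L)
  m <- length(pred)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = (tp + tn) / m, f1 = f1)
}

#' Write predictions to a two-column CSV
#'
#' @param preds a [scored_predictions()].
#' @param path output path; columns `y_true`, `score`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  p <- as_preds(preds)
  utils::write.table(
    data.frame(y_true = p$y_true, score = sprintf("%.17g", p$scores)),
    path, sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
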