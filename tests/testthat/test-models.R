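# Reference classifiers and mutual-information ranking.

test_that("gnb: symmetry at the midpoint of two unit-variance classes", {
  x <- matrix(c(-1.5, -1, -0.5, 0.5, 1, 1.5), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- make_classifier("gnb")
  st <- clf$fit(x, y)
  expect_equal(clf$predict_score(st, matrix(0, 1, 1)), 0.5)
})

test_that("gnb matches the hand-computed Gaussian Bayes rule", {
  # class 0 at {-3, -1}: mu = -2, ML var = 1; class 1 at {1, 3}: mu = 2,
  # var = 1; equal priors
  x <- matrix(c(-3, -1, 1, 3), ncol = 1)
  y <- c(0, 0, 1, 1)
  clf <- make_classifier("gnb")
  st <- clf$fit(x, y)
  xs <- matrix(c(-2, 0, 0.7, 2), ncol = 1)
  expected <- vapply(xs[, 1], function(v) {
    l1 <- dnorm(v, 2, 1) * 0.5
    l0 <- dnorm(v, -2, 1) * 0.5
    l1 / (l0 + l1)
  }, numeric(1))
  expect_equal(clf$predict_score(st, xs), expected, tolerance = 1e-12)
})

test_that("gnb variance floor keeps within-class-constant features finite", {
  x <- cbind(c(1, 1, 2, 2), c(5, 5, 5, 5))
  y <- c(0, 0, 1, 1)
  clf <- make_classifier("gnb")
  st <- clf$fit(x, y)
  p <- clf$predict_score(st, x)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("logistic matches a reference glm fit", {
  d <- small_cohort(n = 150, seed = 21)
  clf <- make_classifier("logistic")
  st <- clf$fit(d$features, d$labels)
  ref <- glm(y ~ ., data = data.frame(y = d$labels, d$features),
             family = binomial())
  expect_equal(unname(st$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(clf$predict_score(st, d$features),
               unname(fitted(ref)), tolerance = 1e-6)
})

test_that("all four classifiers are deterministic and emit probabilities", {
  d <- small_cohort(n = 100, seed = 31)
  for (nm in c("logistic", "gnb", "lda", "random_forest")) {
    clf <- make_classifier(nm, internal_seed = 4L)
    s1 <- clf$predict_score(clf$fit(d$features, d$labels), d$features)
    s2 <- clf$predict_score(clf$fit(d$features, d$labels), d$features)
    expect_identical(s1, s2)
    expect_true(all(is.finite(s1)))
    expect_true(all(s1 >= 0 & s1 <= 1))
  }
  expect_error(make_classifier("svm"), "unknown classifier")
})

test_that("random forest: internal seed fixes the fit; learning happens", {
  d <- small_cohort(n = 150, seed = 41, effect_scale = 2)
  a <- make_classifier("random_forest", internal_seed = 1L, n_trees = 50)
  b <- make_classifier("random_forest", internal_seed = 2L, n_trees = 50)
  sa1 <- a$predict_score(a$fit(d$features, d$labels), d$features)
  sa2 <- a$predict_score(a$fit(d$features, d$labels), d$features)
  sb <- b$predict_score(b$fit(d$features, d$labels), d$features)
  expect_identical(sa1, sa2)
  expect_false(identical(sa1, sb))
  # in-sample AUC of a grown forest should be near-perfect
  expect_gt(auc(scored_predictions(d$labels, sa1)), 0.95)
  # held-out AUC beats chance clearly on a strong signal
  split <- stratified_split(d$labels, 0.3, 1)
  st <- a$fit(d$features[split$train, ], d$labels[split$train])
  oos <- auc(scored_predictions(
    d$labels[split$test],
    a$predict_score(st, d$features[split$test, ])))
  expect_gt(oos, 0.7)
})

test_that("lda survives constant and collinear columns", {
  d <- small_cohort(n = 80, seed = 51)
  x <- cbind(d$features, const = 1, dup = d$features[, 1])
  clf <- make_classifier("lda")
  st <- clf$fit(x, d$labels)
  p <- clf$predict_score(st, x)
  expect_true(all(is.finite(p)))
})

test_that("mutual information: perfect dependence, independence, and the
           hand-computed joint", {
  y <- rep(c(0L, 1L), each = 10)
  x <- cbind(copy = y, const = 0, noise = rep(c(0L, 1L), 10))
  d <- labeled_dataset(x, y)
  r <- mutual_information_rank(d, m = 1)
  h <- -sum(c(.5, .5) * log(c(.5, .5)))
  expect_equal(r$scores[[1]], h)
  expect_equal(r$scores[[2]], 0)
  expect_equal(r$selected, 1L)

  # P(1,1) = P(0,0) = 0.4, P(1,0) = P(0,1) = 0.1 on 10 points
  xj <- c(rep(1L, 4), rep(0L, 4), 1L, 0L)
  yj <- c(rep(1L, 4), rep(0L, 4), 0L, 1L)
  dj <- labeled_dataset(cbind(f = xj), yj)
  mi <- mutual_information_rank(dj, m = 1)$scores[[1]]
  expect_equal(mi, 0.8 * log(1.6) + 0.2 * log(0.4))
  expect_equal(mi, 0.1927, tolerance = 1e-3)
})

test_that("mutual information is invariant under monotone transforms and
           breaks ties by feature index", {
  set.seed(61)
  n <- 400
  v <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * v))
  d1 <- labeled_dataset(cbind(a = v, b = rnorm(n)), y)
  d2 <- labeled_dataset(cbind(a = exp(v), b = rnorm(n)), y)
  expect_equal(mutual_information_rank(d1, 1)$scores[[1]],
               mutual_information_rank(d2, 1)$scores[[1]])

  dup <- labeled_dataset(cbind(u = v, w = v), y)
  r <- mutual_information_rank(dup, m = 2)
  expect_equal(r$order, c(1L, 2L))

  expect_error(mutual_information_rank(
    labeled_dataset(cbind(a = c(1, NA, 3)), c(0, 1, 1)), 1), "missing")
})

test_that("signal features outrank null features on a large cohort", {
  spec <- cohort_spec(2691, 0.19, 18, 9, effect_scale = 1, seed = 71)
  d <- generate_cohort(spec)
  r <- mutual_information_rank(d, m = 10)
  # the generator puts alternating-sign unit weights on features 1..10
  expect_gte(length(intersect(r$selected, 1:10)), 9)
})
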