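# ROC statistics against independent oracles and hand-derived values.

test_that("auc matches hand cases: perfect separation, full ties, mixed", {
  expect_equal(auc(scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9))), 1)
  expect_equal(auc(scored_predictions(c(0, 1, 0, 1), rep(0.3, 4))), 0.5)
  # 4 pairs, 2 concordant: (0.2 vs 0.3) discordant, (0.2 vs 0.6) discordant,
  # (0.9 vs 0.3) and (0.9 vs 0.6) concordant
  expect_equal(auc(scored_predictions(c(0, 1, 0, 1), c(.3, .2, .6, .9))), 0.5)
  expect_error(scored_predictions(c(1, 1), c(.2, .3)), "both classes")
})

test_that("auc equals the pair-enumeration oracle, with and without ties", {
  set.seed(101)
  for (i in 1:50) {
    inst <- random_instance()
    expect_equal(auc(scored_predictions(inst$y, inst$s)),
                 oracle_auc(inst$y, inst$s))
  }
})

test_that("auc is invariant under score negation plus label flip", {
  set.seed(102)
  for (i in 1:20) {
    inst <- random_instance()
    a <- auc(scored_predictions(inst$y, inst$s))
    b <- auc(scored_predictions(1L - inst$y, -inst$s))
    expect_equal(a, b)
  }
})

test_that("roc_curve endpoints, perfect-separation point, tie degeneracy", {
  perfect <- roc_curve(scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9)))
  expect_equal(perfect$fpr[1], 0)
  expect_equal(perfect$tpr[1], 0)
  expect_equal(perfect$fpr[nrow(perfect)], 1)
  expect_equal(perfect$tpr[nrow(perfect)], 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))

  ties <- roc_curve(scored_predictions(c(0, 1), c(.5, .5)))
  expect_equal(ties$fpr, c(0, 1))
  expect_equal(ties$tpr, c(0, 1))
})

test_that("trapezoidal area under roc_curve equals auc", {
  trapezoid <- function(curve) {
    sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  }
  set.seed(103)
  for (i in 1:50) {
    inst <- random_instance()
    p <- scored_predictions(inst$y, inst$s)
    expect_equal(trapezoid(roc_curve(p)), auc(p))
  }
})

test_that("delong_variance: degenerate cases and double-loop oracle", {
  expect_equal(
    delong_variance(scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9))), 0)
  expect_equal(
    delong_variance(scored_predictions(c(0, 1, 0, 1), rep(.5, 4))), 0)
  expect_error(delong_variance(scored_predictions(c(0, 0, 1), c(.1, .2, .9))),
               "at least 2")
  set.seed(104)
  for (i in 1:30) {
    inst <- random_instance(n_max = 30)
    expect_equal(delong_variance(scored_predictions(inst$y, inst$s)),
                 oracle_delong_variance(inst$y, inst$s))
  }
})

test_that("delong_ci: degenerate interval and the Wald arithmetic", {
  perfect <- delong_ci(scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9)))
  expect_equal(perfect$ci_low, perfect$auc)
  expect_equal(perfect$ci_high, perfect$auc)
  # auc 0.5, variance 0.01 at level 0.95: 0.5 +/- 1.959964 * 0.1
  set.seed(105)
  inst <- random_instance()
  ci <- delong_ci(scored_predictions(inst$y, inst$s))
  z <- qnorm(0.975)
  expect_equal(ci$ci_low, max(0, ci$auc - z * sqrt(ci$variance)))
  expect_equal(ci$ci_high, min(1, ci$auc + z * sqrt(ci$variance)))
  expect_equal(0.5 - z * 0.1, 0.304, tolerance = 1e-3)
  expect_equal(0.5 + z * 0.1, 0.696, tolerance = 1e-3)
})

test_that("hanley_mcneil_se: closed-form values and n-scaling", {
  expect_equal(hanley_mcneil_se(1, 10, 10), 0)
  # A=0.5: Q1=Q2=1/3, SE^2 = (0.25 + 8*(1/3 - 0.25)) / 25
  expect_equal(hanley_mcneil_se(0.5, 5, 5),
               sqrt((0.25 + 8 * (1 / 3 - 0.25)) / 25))
  expect_equal(hanley_mcneil_se(0.5, 5, 5), 0.1915, tolerance = 1e-4)
  ses <- vapply(c(10, 50, 100), function(n) hanley_mcneil_se(0.8, n, n),
                numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("independent_roc_test: symmetry, hand-derived z, edge cases", {
  set.seed(106)
  inst <- random_instance()
  p <- scored_predictions(inst$y, inst$s)
  same <- independent_roc_test(p, p)
  expect_equal(same$z, 0)
  expect_equal(same$p_two_sided, 1)

  inst2 <- random_instance()
  q <- scored_predictions(inst2$y, inst2$s)
  ab <- independent_roc_test(p, q)
  ba <- independent_roc_test(q, p)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_two_sided, ba$p_two_sided)

  # A_a = 0.9, A_b = 0.6, n1 = n0 = 10, built from exact concordance
  # counts (90 and 60 of the 100 pairs), checked against a by-hand
  # recomputation of the Q1/Q2 formulas
  ya <- rep(1:0, each = 10)
  pa <- scored_predictions(ya, c(rep(11, 8), 6.5, 4.5, 1:10))
  pb <- scored_predictions(ya, c(rep(11, 6), rep(0.5, 4), 1:10))
  expect_equal(auc(pa), 0.9)
  expect_equal(auc(pb), 0.6)
  hm2 <- function(a, n) {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / n^2
  }
  cmp <- independent_roc_test(pa, pb)
  expect_equal(cmp$z, (0.9 - 0.6) / sqrt(hm2(0.9, 10) + hm2(0.6, 10)))
  expect_equal(cmp$z, 2.016, tolerance = 1e-3)
  expect_equal(cmp$p_two_sided, 0.044, tolerance = 1e-2)

  # delong-SE variant runs and agrees in sign
  dl <- independent_roc_test(p, q, method = "delong")
  expect_equal(sign(dl$z), sign(ab$z))

  # zero pooled SE: both perfect and equal
  perf <- scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  eq <- independent_roc_test(perf, perf)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_sided, 1)
  # zero pooled SE with unequal AUCs (A=1 vs A=0)
  anti <- scored_predictions(c(0, 0, 1, 1), c(.8, .9, .1, .2))
  ne <- independent_roc_test(perf, anti)
  expect_true(is.infinite(ne$z))
  expect_equal(ne$p_two_sided, 0)
})

test_that("accuracy_f1: perfect, all-negative, and balanced hand case", {
  perf <- scored_predictions(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_equal(accuracy_f1(perf), c(accuracy = 1, f1 = 1))
  allneg <- scored_predictions(c(0, 1, 1), c(.1, .2, .3))
  expect_equal(accuracy_f1(allneg)[["f1"]], 0)
  # TP=1, FP=1, FN=1, TN=1
  mixed <- scored_predictions(c(1, 1, 0, 0), c(.9, .4, .6, .1))
  expect_equal(accuracy_f1(mixed), c(accuracy = 0.5, f1 = 0.5))
})

test_that("predictions round-trip through the two-column CSV", {
  set.seed(107)
  inst <- random_instance()
  p <- scored_predictions(inst$y, inst$s)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_predictions(p, path)
  back <- read.csv(path)
  expect_identical(back$y_true, p$y_true)
  expect_identical(back$score, p$scores)
})
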