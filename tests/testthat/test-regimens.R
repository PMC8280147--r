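# Validation regimens: pooling multiplicities, determinism, pooling
# identities for a fit-free scorer, bootstrap out-of-bag behaviour.

test_that("split_validate: stratified hold-out with seeded determinism", {
  d <- small_cohort(n = 120, seed = 1)
  r1 <- split_validate(d, monotone_scorer(), 0.3, seed = 4)
  r2 <- split_validate(d, monotone_scorer(), 0.3, seed = 4)
  expect_identical(r1$pooled$scores, r2$pooled$scores)
  expect_identical(r1$pooled_indices, r2$pooled_indices)
  expect_equal(r1$regimen, "split7030")
  expect_equal(r1$n_train + r1$n_test, 120)

  const <- split_validate(d, constant_scorer(), 0.5, seed = 9)
  expect_equal(const$auc_value, 0.5)
  expect_equal(const$regimen, "split5050")
})

test_that("50/50 split of a 681-row cohort holds out 340 or 341", {
  d <- generate_cohort(cohort_spec(681, 0.54, 6, 2, seed = 2))
  r <- split_validate(d, constant_scorer(), 0.5, seed = 0)
  expect_true(r$n_test %in% c(340L, 341L))
})

test_that("kfold_cv pools every sample exactly once; global AUC equals the
           fixed-scorer full-data AUC", {
  d <- small_cohort(n = 110, seed = 3)
  r <- kfold_cv(d, monotone_scorer(), k = 10, seed = 5)
  expect_equal(sort(r$pooled_indices), seq_len(110))
  full <- auc(scored_predictions(d$labels, plogis(d$features[, 1])))
  expect_equal(r$auc_value, full)
  expect_equal(kfold_cv(d, constant_scorer(), 10, 1)$auc_value, 0.5)
  expect_error(kfold_cv(small_cohort(30, seed = 4), monotone_scorer(),
                        k = 25, seed = 1), "at least k")
})

test_that("repeated_kfold pools each sample exactly `repeats` times and
           reduces to kfold_cv at repeats = 1", {
  d <- small_cohort(n = 60, seed = 5)
  r <- repeated_kfold(d, monotone_scorer(), k = 5, repeats = 3, seed = 7)
  expect_length(r$pooled_indices, 3 * 60)
  expect_true(all(tabulate(r$pooled_indices, 60) == 3))
  full <- auc(scored_predictions(d$labels, plogis(d$features[, 1])))
  expect_equal(r$auc_value, full)

  single <- repeated_kfold(d, monotone_scorer(), k = 5, repeats = 1, seed = 7)
  base <- kfold_cv(d, monotone_scorer(), k = 5, seed = 7)
  expect_identical(single$pooled$scores, base$pooled$scores)
  expect_identical(single$pooled_indices, base$pooled_indices)
})

test_that("bootstrap_validate: train multiset of size n, OOB scoring,
           seeded reproducibility", {
  d <- small_cohort(n = 80, seed = 9)
  r <- bootstrap_validate(d, monotone_scorer(), n_reps = 25, seed = 3)
  expect_length(r$per_rep_aucs, 25)
  expect_true(all(r$train_sizes == 80))
  expect_equal(r$auc_value, mean(r$per_rep_aucs))
  expect_equal(r$auc_aggregation, "mean_of_reps")
  # replicate draws are recomputable from the derived sub-seeds
  redo <- bootstrap_validate(d, monotone_scorer(), n_reps = 25, seed = 3)
  expect_identical(r$pooled$scores, redo$pooled$scores)
  expect_identical(r$pooled_indices, redo$pooled_indices)
  # OOB sets never intersect their replicate's training multiset
  first_oob <- r$pooled_indices[seq_len(round(r$oob_fractions[1] * 80))]
  train1 <- local({
    set.seed(derive_seed(3, 1))
    sample.int(80, 80, replace = TRUE)
  })
  expect_length(train1, 80)
  expect_length(intersect(first_oob, train1), 0)

  expect_equal(
    bootstrap_validate(d, constant_scorer(), 10, 1)$per_rep_aucs,
    rep(0.5, 10))
  tiny <- labeled_dataset(matrix(rnorm(16), ncol = 2), rep(c(0, 1), 4))
  expect_error(bootstrap_validate(tiny, monotone_scorer(), 5, 1), "n >= 10")
})

test_that("bootstrap redraws degenerate out-of-bag replicates", {
  # 2 positives in 12 rows: many bootstrap draws capture both positives,
  # leaving a single-class OOB set that must be redrawn
  x <- matrix(rnorm(24), ncol = 2)
  y <- c(1, 1, rep(0, 10))
  d <- labeled_dataset(x, y)
  r <- bootstrap_validate(d, constant_scorer(), n_reps = 40, seed = 2)
  expect_length(r$per_rep_aucs, 40)
  expect_gt(r$n_redraws, 0)
})

test_that("loo_validate is seed-free, pools each sample once, and matches
           the fixed-scorer full-data AUC", {
  d <- small_cohort(n = 40, seed = 11)
  r1 <- loo_validate(d, monotone_scorer())
  r2 <- loo_validate(d, monotone_scorer())
  expect_identical(r1$pooled$scores, r2$pooled$scores)
  expect_equal(r1$pooled_indices, seq_len(40))
  full <- auc(scored_predictions(d$labels, plogis(d$features[, 1])))
  expect_equal(r1$auc_value, full)

  tiny <- labeled_dataset(matrix(rnorm(8), ncol = 2), c(1, 0, 0, 0))
  expect_error(loo_validate(tiny, monotone_scorer()), ">= 2 members")
})

test_that("run_regimen dispatches tags and rejects unknown ones", {
  d <- small_cohort(n = 60, seed = 13)
  expect_equal(run_regimen(d, constant_scorer(), "split7030", 1)$regimen,
               "split7030")
  expect_equal(run_regimen(d, constant_scorer(), "kfold5", 1)$regimen,
               "kfold5")
  expect_equal(run_regimen(d, constant_scorer(), "repeated2x5", 1)$regimen,
               "repeated2x5")
  expect_equal(run_regimen(d, constant_scorer(), "bootstrap10", 1)$regimen,
               "bootstrap10")
  expect_equal(run_regimen(d, constant_scorer(), "loo")$regimen, "loo")
  expect_error(run_regimen(d, constant_scorer(), "holdout"), "unknown")
})

test_that("regimen results are bit-reproducible across models sharing a
           seed: the partition depends only on (regimen, seed)", {
  d <- small_cohort(n = 90, seed = 15)
  for (tag in c("split7030", "kfold5", "repeated2x5", "bootstrap10")) {
    ra <- run_regimen(d, monotone_scorer(), tag, 6)
    rb <- run_regimen(d, constant_scorer(), tag, 6)
    expect_identical(ra$pooled_indices, rb$pooled_indices)
  }
})
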