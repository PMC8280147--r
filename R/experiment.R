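# The seed-replication harness: run one regimen across many seeds for a
# battery of classifiers (splits depend only on the seed, never on the
# classifier), locate the extreme AUCs, attach DeLong intervals to the
# extreme seeds' pooled predictions, and test max vs min with the
# independent two-ROC comparison.

#' Replicate a validation regimen across seeds
#'
#' For each seed `s` in `seeds`, every classifier is validated under the
#' identical data partition (the partition is a deterministic function of
#' `(regimen, s)` alone). Per classifier, the per-seed AUCs are collected;
#' the seeds attaining the maximum and minimum AUC (ties resolved to the
#' lowest seed) are re-run to recover their pooled predictions, DeLong
#' confidence intervals are computed on those, and the two prediction sets
#' are compared with the non-directional independent ROC test. For the
#' seed-free `loo` regimen a single run is performed and no extremes or
#' comparison are produced.
#'
#' A failed (classifier, seed) cell is logged and skipped; a classifier
#' with more than 10% failed seeds aborts the run.
#'
#' @param data a `labeled_dataset` with no missing cells.
#' @param classifiers list of classifiers (see [make_classifier()],
#'   [default_classifiers()]).
#' @param regimen regimen tag understood by [run_regimen()].
#' @param n_seeds number of replication seeds; the seeds are
#'   `0 .. n_seeds - 1` unless `seeds` is given.
#' @param seeds optional explicit integer seed vector.
#' @param comparison_method SE method for the max-vs-min test,
#'   `"hanley_mcneil"` (default) or `"delong"`.
#' @param level confidence level for the DeLong intervals.
#' @return list of `stability_report` objects, one per classifier, each
#'   with fields `regimen`, `classifier`, `n_seeds`, `seeds`, `aucs`,
#'   `max_auc`, `min_auc`, `range`, `max_seed`, `min_seed`, `ci_max`,
#'   `ci_min`, `comparison`, `significance`, `failed_seeds`, and `caveat`
#'   (the max/min prediction sets share the underlying rows, so treating
#'   them as independent is an approximation inherited from the design).
#' @export
run_stability <- function(data, classifiers, regimen, n_seeds = 100L,
                          seeds = NULL,
                          comparison_method = c("hanley_mcneil", "delong"),
                          level = 0.95) {
  stopifnot(inherits(data, "labeled_dataset"), length(classifiers) >= 1)
  comparison_method <- match.arg(comparison_method)
  if (regimen == "loo") {
    reports <- lapply(classifiers, function(clf) {
      res <- loo_validate(data, clf)
      structure(
        list(
          regimen = regimen, classifier = clf$name, n_seeds = 1L,
          seeds = NA_integer_, aucs = res$auc_value,
          max_auc = res$auc_value, min_auc = res$auc_value, range = 0,
          max_seed = NA_integer_, min_seed = NA_integer_,
          ci_max = delong_ci(res$pooled, level),
          ci_min = delong_ci(res$pooled, level),
          comparison = NULL, significance = "ns",
          failed_seeds = integer(0), caveat = "loo: seed-free, no extremes"
        ),
        class = "stability_report"
      )
    })
    return(reports)
  }
  seeds <- as.integer(seeds %||% (seq_len(n_seeds) - 1L))
  stopifnot(length(seeds) >= 2)
  lapply(classifiers, function(clf) {
    aucs <- rep(NA_real_, length(seeds))
    for (i in seq_along(seeds)) {
      res <- tryCatch(run_regimen(data, clf, regimen, seeds[i]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("seed %d failed for %s: %s",
                        seeds[i], clf$name, conditionMessage(res)))
        next
      }
      aucs[i] <- res$auc_value
    }
    failed <- seeds[is.na(aucs)]
    if (length(failed) > 0.1 * length(seeds)) {
      stop(sprintf("classifier %s: %d of %d seeds failed",
                   clf$name, length(failed), length(seeds)))
    }
    ok <- which(!is.na(aucs))
    i_max <- ok[which.max(aucs[ok])]   # which.max takes the first = lowest seed
    i_min <- ok[which.min(aucs[ok])]
    # re-run the two extreme seeds: regimens are deterministic in the seed,
    # so this reproduces their pooled predictions without storing all seeds
    res_max <- run_regimen(data, clf, regimen, seeds[i_max])
    res_min <- run_regimen(data, clf, regimen, seeds[i_min])
    comparison <- independent_roc_test(res_max$pooled, res_min$pooled,
                                       method = comparison_method)
    structure(
      list(
        regimen = regimen, classifier = clf$name,
        n_seeds = length(seeds), seeds = seeds, aucs = aucs,
        max_auc = aucs[i_max], min_auc = aucs[i_min],
        range = aucs[i_max] - aucs[i_min],
        max_seed = seeds[i_max], min_seed = seeds[i_min],
        ci_max = delong_ci(res_max$pooled, level),
        ci_min = delong_ci(res_min$pooled, level),
        comparison = comparison,
        significance = significance_tag(comparison$p_two_sided),
        failed_seeds = failed,
        caveat = paste("max/min prediction sets overlap in source rows;",
                       "independence is an approximation")
      ),
      class = "stability_report"
    )
  })
}

significance_tag <- function(p) {
  if (is.null(p) || is.na(p)) "ns"
  else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05"
  else "ns"
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %s / %s: %d seeds, AUC max %.3f (seed %s) min %.3f (seed %s), range %.3f [%s]\n",
    x$classifier, x$regimen, x$n_seeds, x$max_auc, format(x$max_seed),
    x$min_auc, format(x$min_seed), x$range, x$significance))
  invisible(x)
}

star_suffix <- function(significance) {
  switch(significance, "p<0.01" = "**", "p<0.05" = "*", "")
}

#' Format stability reports as a max/min estimate table
#'
#' One row per `classifier x {Max, Min}`, one column per regimen; each cell
#' is `"AUC [lo-hi]"` from the extreme seed's DeLong interval, suffixed
#' `*` for p < 0.05 and `**` for p < 0.01 in the max-vs-min independent
#' ROC comparison.
#'
#' @param reports list of `stability_report` objects (possibly covering
#'   several regimens).
#' @return a data frame with a `Method` column and one column per regimen.
#' @export
summarize_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  regimens <- unique(vapply(reports, `[[`, "", "regimen"))
  classifiers <- unique(vapply(reports, `[[`, "", "classifier"))
  rows <- as.vector(t(outer(classifiers, c("Max", "Min"), paste, sep = ": ")))
  out <- data.frame(Method = rows, check.names = FALSE,
                    stringsAsFactors = FALSE)
  cell <- function(value, est, star) {
    sprintf("%.3f [%.3f-%.3f]%s", value, est$ci_low, est$ci_high, star)
  }
  for (rg in regimens) {
    col <- rep(NA_character_, length(rows))
    for (rep_ in reports) {
      if (rep_$regimen != rg) next
      star <- star_suffix(rep_$significance)
      i <- match(paste0(rep_$classifier, ": Max"), rows)
      # cells show the regimen's AUC at the extreme seed next to the DeLong
      # CI of that seed's pooled predictions; for the bootstrap the AUC is
      # a mean of replicate AUCs and can fall outside its pooled-CI
      col[i] <- cell(rep_$max_auc, rep_$ci_max, star)
      col[i + 1] <- cell(rep_$min_auc, rep_$ci_min, star)
    }
    out[[rg]] <- col
  }
  out
}

#' Long-format AUC ranges for plotting
#'
#' One row per (classifier, regimen) with the AUC range max - min over
#' seeds. Seed-free `loo` reports are omitted (no range is defined).
#' Ordering is stable by (classifier, regimen).
#'
#' @param reports list of `stability_report` objects.
#' @return data frame with columns `classifier`, `regimen`, `range`.
#' @export
summarize_ranges <- function(reports) {
  stopifnot(length(reports) >= 1)
  keep <- Filter(function(r) r$regimen != "loo", reports)
  out <- data.frame(
    classifier = vapply(keep, `[[`, "", "classifier"),
    regimen = vapply(keep, `[[`, "", "regimen"),
    range = vapply(keep, `[[`, 0, "range"),
    stringsAsFactors = FALSE
  )
  out[order(out$classifier, out$regimen), , drop = FALSE]
}

#' Per-seed AUC matrix in long format
#'
#' @param reports list of `stability_report` objects.
#' @return data frame with columns `regimen`, `classifier`, `seed`, `auc`.
#' @export
collect_aucs <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(regimen = r$regimen, classifier = r$classifier,
               seed = r$seeds, auc = r$aucs, stringsAsFactors = FALSE)
  }))
}
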