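# Orchestration: config-driven pipeline from (generated or loaded) dataset
# through preprocessing and the stability experiment to the report
# artifacts, plus the `validstab` command-line entry point. All randomness
# is driven by seeds recorded in the config, so re-running an identical
# config reproduces every CSV byte for byte.

#' Run the full stability pipeline from a config
#'
#' The config is a JSON file (or an equivalent named list) with fields:
#' \describe{
#'   \item{dataset}{either `list(path=, label_column=)` pointing at a CSV,
#'     or `list(cohort=)` with [cohort_spec()] fields (plus optional
#'     `target_auc` / `calibration_tolerance`, in which case
#'     [calibrate_effect_scale()] sets the signal strength first).}
#'   \item{preprocessing}{`"drop"`, `"impute"`, or `"none"`.}
#'   \item{classifiers}{character vector of classifier tags.}
#'   \item{internal_seed}{internal seed for the random forest (default 0).}
#'   \item{regimens}{character vector of regimen tags for [run_regimen()].}
#'   \item{n_seeds}{number of replication seeds (default 100; seeds are
#'     `0..n_seeds-1`).}
#'   \item{comparison_method}{`"hanley_mcneil"` (default) or `"delong"`.}
#'   \item{feature_selection}{`"off"` (default) or
#'     `list(method="mutual_info", m=)`.}
#' }
#' Two presets mirroring the motivating cohorts ship with the package:
#' `system.file("configs", "primary_cohort.json", package = "validstab")`
#' and `"secondary_cohort.json"`.
#'
#' Artifacts written to `out_dir`: `table.csv` (max/min estimate table),
#' `ranges.csv` (long-format AUC ranges), `aucs.csv` (per-seed AUCs),
#' `run_log.json` (config, seeds, effective hyperparameters, version).
#'
#' @param config path to a JSON config or a named list.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the list of `stability_report` objects, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  data <- resolve_dataset(cfg, say)
  policy <- cfg$preprocessing %||% "none"
  data <- switch(policy,
    drop = complete_case_filter(data),
    impute = mean_impute(data),
    none = data,
    stop("unknown preprocessing policy: '", policy, "'")
  )
  if (anyNA(data$features)) {
    stop("dataset still has missing cells; choose policy 'drop' or 'impute'")
  }
  say("dataset: %d rows, %d features, prevalence %.3f",
      length(data$labels), ncol(data$features), mean(data$labels))

  fs <- cfg$feature_selection %||% "off"
  ranking <- NULL
  if (!identical(fs, "off")) {
    if (!identical(fs$method, "mutual_info")) {
      stop("unknown feature_selection method")
    }
    ranking <- mutual_information_rank(data, m = fs$m)
    data <- labeled_dataset(
      data$features[, ranking$selected, drop = FALSE],
      data$labels,
      feature_names = data$feature_names[ranking$selected],
      feature_kinds = data$feature_kinds[ranking$selected]
    )
    say("feature selection: kept %d features by mutual information", fs$m)
  }

  tags <- cfg$classifiers %||% c("logistic", "gnb", "lda", "random_forest")
  internal_seed <- cfg$internal_seed %||% 0L
  classifiers <- lapply(tags, make_classifier, internal_seed = internal_seed)
  regimens <- cfg$regimens %||%
    c("split5050", "split7030", "kfold10", "repeated10x10",
      "bootstrap500", "loo")
  n_seeds <- cfg$n_seeds %||% 100L
  method <- cfg$comparison_method %||% "hanley_mcneil"

  reports <- list()
  for (rg in regimens) {
    say("regimen %s (%d seeds, %d classifiers)...", rg,
        if (rg == "loo") 1L else n_seeds, length(classifiers))
    reports <- c(reports,
                 run_stability(data, classifiers, rg, n_seeds = n_seeds,
                               comparison_method = method))
  }

  write.csv(summarize_table(reports), file.path(out_dir, "table.csv"),
            row.names = FALSE)
  write.csv(summarize_ranges(reports), file.path(out_dir, "ranges.csv"),
            row.names = FALSE)
  write.csv(collect_aucs(reports), file.path(out_dir, "aucs.csv"),
            row.names = FALSE)
  log <- list(
    package = "validstab",
    version = as.character(utils::packageVersion("validstab")),
    config = cfg,
    n_rows = length(data$labels),
    prevalence = mean(data$labels),
    seeds = if (all(regimens == "loo")) NA else seq_len(n_seeds) - 1,
    classifiers = lapply(classifiers, function(c_) {
      list(name = c_$name, internal_seed = c_$internal_seed,
           hyperparameters = c_$hyperparameters)
    }),
    feature_ranking = if (!is.null(ranking)) {
      list(selected = ranking$selected, scores = ranking$scores)
    }
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("artifacts written to %s", out_dir)
  invisible(reports)
}

resolve_dataset <- function(cfg, say) {
  src <- cfg$dataset
  if (is.null(src)) stop("config lacks a `dataset` entry")
  if (!is.null(src$path)) {
    say("reading dataset from %s", src$path)
    return(read_dataset(src$path, src$label_column %||% "label"))
  }
  if (!is.null(src$cohort)) {
    co <- src$cohort
    spec <- cohort_spec(
      n_patients = co$n_patients, prevalence = co$prevalence,
      n_continuous = co$n_continuous, n_binary = co$n_binary,
      feature_correlation = co$feature_correlation %||% 0.2,
      effect_scale = co$effect_scale %||% 1,
      n_informative = co$n_informative,
      missing_fraction = co$missing_fraction %||% 0,
      seed = co$seed %||% 0L
    )
    if (!is.null(co$target_auc)) {
      say("calibrating effect scale to oracle AUC %.3f", co$target_auc)
      spec$effect_scale <- calibrate_effect_scale(
        spec, co$target_auc,
        tolerance = co$calibration_tolerance %||% 0.005
      )
      say("calibrated effect_scale = %.4f", spec$effect_scale)
    }
    return(generate_cohort(spec))
  }
  stop("`dataset` must carry either `path` or `cohort`")
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a synthetic cohort CSV + JSON sidecar),
#' `preprocess` (apply a missing-data policy to a CSV), `run` (the full
#' pipeline), `report` (reformat a previous run's artifacts). Invoke from a
#' shell as
#' `Rscript -e 'validstab::validstab_cli()' <subcommand> [options]`, or via
#' the wrapper script in `system.file("cli", "validstab", package =
#' "validstab")`.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   trailing arguments of the Rscript invocation).
#' @return exit status, invisibly (0 on success).
#' @export
validstab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: validstab <generate|preprocess|run|report> [options]",
    "  generate   --config <json> [--seed <int>] --out <csv>",
    "  preprocess --input <csv> --policy drop|impute --out <csv>",
    "  run        --config <json> --out <dir> [--log-level info|quiet]",
    "  report     --aucs <aucs.csv> --out <dir>",
    sep = "\n")
  if (length(args) < 1) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
  }
  status <- tryCatch({
    switch(sub,
      generate = {
        cfg <- jsonlite::read_json(opt("--config"), simplifyVector = TRUE)
        co <- cfg$dataset$cohort %||% cfg$cohort %||%
          stop("config lacks a cohort description")
        seed <- as.integer(opt("--seed", co$seed %||% 0L))
        co$seed <- seed
        ds <- resolve_dataset(list(dataset = list(cohort = co)), message)
        write_cohort(ds, opt("--out") %||% stop("--out required"))
        0L
      },
      preprocess = {
        ds <- read_dataset(opt("--input") %||% stop("--input required"))
        pol <- opt("--policy") %||% stop("--policy required")
        ds <- switch(pol, drop = complete_case_filter(ds),
                     impute = mean_impute(ds),
                     stop("policy must be drop or impute"))
        write_dataset(ds, opt("--out") %||% stop("--out required"))
        0L
      },
      run = {
        run_pipeline(opt("--config") %||% stop("--config required"),
                     opt("--out") %||% stop("--out required"),
                     quiet = identical(opt("--log-level", "info"), "quiet"))
        0L
      },
      report = {
        aucs <- read.csv(opt("--aucs") %||% stop("--aucs required"))
        out_dir <- opt("--out") %||% stop("--out required")
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        agg <- stats::aggregate(auc ~ classifier + regimen, aucs,
                                function(v) max(v) - min(v))
        names(agg)[3] <- "range"
        agg <- agg[agg$regimen != "loo", c("classifier", "regimen", "range")]
        agg <- agg[order(agg$classifier, agg$regimen), ]
        write.csv(agg, file.path(out_dir, "ranges.csv"), row.names = FALSE)
        0L
      },
      {
        message(usage)
        1L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
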