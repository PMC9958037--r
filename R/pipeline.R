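#' End-to-end run configuration
#'
#' Bundles every knob of the simulate - quantify - classify - compare
#' pipeline with the study defaults: 16 hidden neurons and a fixed decision
#' threshold of 0.5, training and evaluating on all subjects.
#'
#' @param seed Master seed for the run (cohort generation and model fit).
#' @param cohort A [cohort_config()].
#' @param render Render pixel-level cines (`TRUE`) or quantify from the
#'   waveform flux curves (`FALSE`, faster, noise-free).
#' @param split Forward/backward split mode for [batch_qflow()].
#' @param ratio Second GSV/PV ratio feature, `"mf"` or `"mv"`.
#' @param standardize Standardize features before the RBF layer.
#' @param k,eta,epochs RBFNN hyperparameters.
#' @param threshold Decision threshold: a number (default 0.5) or
#'   `"sweep"` for F-measure selection on the training data.
#' @param welch Welch's t statistic in the group comparison.
#' @param out_dir Optional output directory for run artifacts.
#' @param write_cine Also write the cine/mask NIfTI volumes when `out_dir`
#'   is set (default `FALSE`; they are large).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 42L, cohort = cohort_config(), render = TRUE,
                       split = "phase", ratio = "mf", standardize = TRUE,
                       k = 16L, eta = 0.5, epochs = 1000L, threshold = 0.5,
                       welch = FALSE, out_dir = NULL, write_cine = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full venous-reflux analysis pipeline
#'
#' Executes, in order: synthetic cohort generation, QFlow quantification of
#' every subject-setpoint, feature assembly, RBFNN training on all subjects
#' (the training set is also the evaluation set, as in a training-stage
#' report), confusion-matrix metrics at the configured threshold, and the
#' per-segment group comparison. A stage failure marks the stage in the
#' report and preserves the artifacts of completed stages.
#'
#' Given the same `run_config` the report is reproduced exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory override; when set, writes `qflow.csv`,
#'   `features.csv`, `scores.csv`, `compare.csv`, `model.json` and
#'   `report.json` (plus the cohort NIfTI files if `write_cine`).
#' @return A list of class `veinflow_run`: `config`, `cohort`, `qflow`,
#'   `features`, `model`, `scores` (per-subject score table), `confusion`,
#'   `metrics`, `comparison`, `stages` (status table) and `version`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config,
                 version = as.character(packageVersion("veinflow")))
  stages <- list()
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$msg)
    if (!res$ok) NULL else res$value
  }

  report$cohort <- stage("simulate",
    generate_cohort(config$cohort, seed = config$seed, render = config$render))
  if (!is.null(report$cohort)) {
    report$qflow <- stage("qflow", batch_qflow(report$cohort, split = config$split))
  }
  if (!is.null(report$qflow)) {
    labels <- cohort_labels(report$cohort)
    report$features <- stage("features",
      build_features(report$qflow, labels, ratio = config$ratio))
  }
  if (!is.null(report$features)) {
    report$model <- stage("train",
      rbfnn_fit(report$features, k = config$k, eta = config$eta,
                epochs = config$epochs, seed = config$seed,
                threshold = config$threshold,
                standardize = config$standardize))
  }
  if (!is.null(report$model)) {
    report$scores <- stage("evaluate", {
      sc <- predict(report$model, report$features, type = "score")
      tibble(subject_id = report$features$subject_id,
             label = report$features$label,
             score = sc,
             predicted = as.integer(sc > report$model$threshold))
    })
  }
  if (!is.null(report$scores)) {
    report$confusion <- confusion_matrix(report$scores$label,
                                         report$scores$predicted)
    report$metrics <- classification_metrics(report$confusion)
  }
  if (!is.null(report$qflow)) {
    report$comparison <- stage("compare",
      compare_segments(report$qflow, welch = config$welch))
  }
  report$stages <- tibble(stage = names(stages),
                          status = unlist(stages, use.names = FALSE))
  class(report) <- "veinflow_run"
  if (!is.null(out_dir)) write_run(report, out_dir)
  report
}

write_run <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  drop_lists <- function(df) df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  if (!is.null(report$qflow)) {
    readr::write_csv(report$qflow, file.path(out_dir, "qflow.csv"))
  }
  if (!is.null(report$features)) {
    readr::write_csv(report$features, file.path(out_dir, "features.csv"))
  }
  if (!is.null(report$scores)) {
    readr::write_csv(report$scores, file.path(out_dir, "scores.csv"))
  }
  if (!is.null(report$comparison)) {
    readr::write_csv(report$comparison, file.path(out_dir, "compare.csv"))
  }
  if (!is.null(report$model)) {
    write_rbfnn(report$model, file.path(out_dir, "model.json"))
  }
  if (!is.null(report$cohort) && isTRUE(report$config$write_cine)) {
    write_cohort(report$cohort, file.path(out_dir, "cohort"))
  }
  digest <- list(
    seed = report$config$seed,
    version = report$version,
    n_subjects = if (!is.null(report$cohort)) nrow(cohort_labels(report$cohort)),
    threshold = if (!is.null(report$model)) report$model$threshold,
    confusion = if (!is.null(report$confusion)) as.list(drop_lists(report$confusion)),
    metrics = if (!is.null(report$metrics)) as.list(drop_lists(report$metrics)),
    comparison = if (!is.null(report$comparison)) report$comparison,
    stages = report$stages)
  jsonlite::write_json(digest, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.veinflow_run <- function(x, ...) {
  cat("<veinflow_run>\n")
  print(x$stages)
  if (!is.null(x$metrics)) {
    cat(sprintf(
      "threshold %.2f | sensitivity %.2f%% | precision %.2f%% | accuracy %.2f%% | F %.2f%%\n",
      x$model$threshold, x$metrics$sensitivity, x$metrics$precision,
      x$metrics$accuracy, x$metrics$f_measure))
  }
  if (!is.null(x$comparison)) {
    sig <- dplyr::filter(x$comparison, .data$tier %in% c("*", "**", "***"))
    cat(sprintf("significant group differences (raw p < 0.05): %s\n",
                if (nrow(sig) == 0) "none" else
                  paste(sig$segment, toupper(sig$parameter), collapse = ", ")))
  }
  invisible(x)
}
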