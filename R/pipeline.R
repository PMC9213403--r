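#' The four binary quality-classification tasks
#'
#' Positive-class conventions: `good` is the positive class for the three
#' tasks involving good quality, and `eye_abnormality` for the poor-subtype
#' task (probability 1 = eye-abnormality end of the scale).
#'
#' @return A tibble with columns `name`, `positive`, `negative`.
#' @export
task_specs <- function() {
  tibble::tribble(
    ~name,             ~positive,          ~negative,
    "good_vs_poor",    "good",             "poor",
    "good_vs_eaapq",   "good",             "eye_abnormality",
    "good_vs_aapq",    "good",             "artefact",
    "eaapq_vs_aapq",   "eye_abnormality",  "artefact"
  )
}

# subset manifest rows and derive the task's binary labels + subtype detail
.task_data <- function(manifest, task) {
  lab <- manifest$label
  sub <- manifest$poor_subtype
  detail <- if ("degradation" %in% names(manifest)) {
    ifelse(!is.na(manifest$abnormality_kind), manifest$abnormality_kind,
           manifest$degradation)
  } else manifest$abnormality_kind
  pick <- switch(task,
    good_vs_poor = rep(TRUE, nrow(manifest)),
    good_vs_eaapq = lab == "good" | sub == "eye_abnormality",
    good_vs_aapq = lab == "good" | sub == "artefact",
    eaapq_vs_aapq = sub %in% c("eye_abnormality", "artefact"),
    stop(sprintf("unknown task '%s'", task), call. = FALSE)
  )
  y <- switch(task,
    good_vs_poor = ifelse(lab == "good", "good", "poor"),
    good_vs_eaapq = ifelse(lab == "good", "good", "eye_abnormality"),
    good_vs_aapq = ifelse(lab == "good", "good", "artefact"),
    eaapq_vs_aapq = sub
  )
  list(pick = pick, y = y[pick], detail = detail[pick])
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory for all artifacts.
#' @param synth A [dataset_spec()] to generate a dataset, or NULL when
#'   `manifest` points at an existing one.
#' @param manifest Path to an existing manifest CSV (ignored when `synth` is
#'   given).
#' @param features A [feature_config()].
#' @param tasks Task names (subset of [task_specs()]).
#' @param train_fraction Stratified train share (default 0.70).
#' @param cv_folds Folds for the SVM cross-validation stage (default 10).
#' @param alpha Elastic-net mixing parameter.
#' @param rf_trees Trees in the random-forest stage.
#' @param external_manifest Optional path to an external-validation manifest.
#' @param rng_seed Master seed; every stage seed derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       synth = dataset_spec(),
                       manifest = NULL,
                       features = feature_config(),
                       tasks = task_specs()$name,
                       train_fraction = 0.70,
                       cv_folds = 10,
                       alpha = 0.5,
                       rf_trees = 500,
                       external_manifest = NULL,
                       rng_seed = 1L) {
  bad <- setdiff(tasks, task_specs()$name)
  if (length(bad)) stop_param("tasks", paste("unknown:", paste(bad, collapse = ", ")))
  structure(
    list(out_dir = out_dir, synth = synth, manifest = manifest,
         features = features, tasks = tasks, train_fraction = train_fraction,
         cv_folds = cv_folds, alpha = alpha, rf_trees = rf_trees,
         external_manifest = external_manifest,
         rng_seed = as.integer(rng_seed)),
    class = "run_config"
  )
}

.log_line <- function(log_path, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  message(line)
}

#' Run the end-to-end quality-assessment pipeline
#'
#' Executes synthesis (optional) -> feature extraction -> stratified 70/30
#' split -> per task: elastic-net selection + random-forest training with a
#' held-out test report, and a pooled k-fold SVM cross-validation report ->
#' optional external-validation report. Writes the manifest, the feature
#' matrix, per-task reports (JSON + ROC CSV) and a machine-readable summary
#' (per task: testing Se/Sp/Acc/AUC and cross-validation Se/Sp/Acc/AUC) under
#' `config$out_dir`. A failed stage writes a `FAILED` marker naming the stage
#' and rethrows; partial outputs are retained.
#'
#' @param config A [run_config()].
#' @return An object of class `fqc_run`: the summary tibble, per-task
#'   reports, fitted models and the output directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_param("config", "must be a run_config")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  stage <- "init"
  result <- tryCatch({
    seed <- config$rng_seed
    .log_line(log_path, "pipeline start, master seed %d", seed)

    stage <- "synth"
    manifest <- if (!is.null(config$synth)) {
      .log_line(log_path, "synth: generating dataset (seed %d)", derive_seed(seed, 1L))
      generate_dataset(config$synth, file.path(out, "images"),
                       rng_seed = derive_seed(seed, 1L))
    } else {
      read_manifest(config$manifest)
    }
    write_manifest(manifest, file.path(out, "manifest.csv"))

    stage <- "extract"
    .log_line(log_path, "extract: %d images", nrow(manifest))
    feats <- extract_features_batch(manifest, config$features)
    utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)

    stage <- "split"
    manifest <- stratified_split(manifest, config$train_fraction,
                                 rng_seed = derive_seed(seed, 2L))
    write_manifest(manifest, file.path(out, "manifest.csv"))
    .log_line(log_path, "split: %d train / %d test",
              sum(manifest$split == "train"), sum(manifest$split == "test"))

    external <- NULL
    ext_feats <- NULL
    if (!is.null(config$external_manifest)) {
      stage <- "external-extract"
      external <- read_manifest(config$external_manifest)
      ext_feats <- extract_features_batch(external, config$features)
    }

    X <- as.matrix(feats[, -1, drop = FALSE])
    task_results <- list()
    summary_rows <- list()
    for (task in config$tasks) {
      stage <- paste0("task-", task)
      spec <- task_specs()[task_specs()$name == task, ]
      td <- .task_data(manifest, task)
      Xt <- X[td$pick, , drop = FALSE]
      yt <- td$y
      split_t <- manifest$split[td$pick]
      tr <- split_t == "train"
      tdir <- file.path(out, task)
      dir.create(tdir, showWarnings = FALSE)

      sel <- fit_elastic_net(Xt[tr, , drop = FALSE], yt[tr],
                             alpha = config$alpha,
                             rng_seed = derive_seed(seed, 10L),
                             positive_class = spec$positive)
      .log_line(log_path, "%s: lambda %.5g, %d features selected",
                task, sel$chosen_lambda, nrow(sel$selected))
      rf <- train_classifier(Xt[tr, , drop = FALSE], yt[tr], sel,
                             kind = "random_forest",
                             hyperparams = list(ntree = config$rf_trees),
                             rng_seed = derive_seed(seed, 11L),
                             positive_class = spec$positive,
                             negative_class = spec$negative)
      test_report <- quality_report(yt[!tr], predict_proba(rf, Xt[!tr, , drop = FALSE]),
                                    positive_class = spec$positive,
                                    negative_class = spec$negative,
                                    subtypes = td$detail[!tr])
      cv <- crossvalidate(Xt, yt, k = config$cv_folds, kind = "svm",
                          positive_class = spec$positive, alpha = config$alpha,
                          rng_seed = derive_seed(seed, 12L),
                          subtypes = td$detail)
      ext_report <- NULL
      if (!is.null(external)) {
        etd <- .task_data(external, task)
        if (length(unique(etd$y)) == 2) {
          Xe <- as.matrix(ext_feats[, -1, drop = FALSE])[etd$pick, , drop = FALSE]
          ext_report <- quality_report(etd$y, predict_proba(rf, Xe),
                                       positive_class = spec$positive,
                                       negative_class = spec$negative,
                                       subtypes = etd$detail)
        }
      }

      .write_report_json(test_report, file.path(tdir, "test_report.json"))
      utils::write.csv(test_report$roc$points, file.path(tdir, "test_roc.csv"),
                       row.names = FALSE)
      .write_report_json(cv$report, file.path(tdir, "cv_report.json"))
      utils::write.csv(cv$report$roc$points, file.path(tdir, "cv_roc.csv"),
                       row.names = FALSE)
      if (!is.null(ext_report)) {
        .write_report_json(ext_report, file.path(tdir, "external_report.json"))
      }
      jsonlite::write_json(
        list(chosen_lambda = sel$chosen_lambda, alpha = config$alpha,
             selected = sel$selected$feature, rng_seed = sel$rng_seed),
        file.path(tdir, "selection.json"), auto_unbox = TRUE, digits = NA)

      row <- tibble::tibble(
        task = task,
        test_sensitivity = test_report$metrics$sensitivity,
        test_specificity = test_report$metrics$specificity,
        test_accuracy = test_report$metrics$accuracy,
        test_auc = round(test_report$auc, 3),
        cv_sensitivity = cv$report$metrics$sensitivity,
        cv_specificity = cv$report$metrics$specificity,
        cv_accuracy = cv$report$metrics$accuracy,
        cv_auc = round(cv$report$auc, 3)
      )
      if (!is.null(ext_report)) {
        row$external_accuracy <- ext_report$metrics$accuracy
        row$external_auc <- round(ext_report$auc, 3)
      }
      summary_rows[[task]] <- row
      task_results[[task]] <- list(selection = sel, rf = rf,
                                   test_report = test_report, cv = cv,
                                   external_report = ext_report)
      .log_line(log_path,
                "%s: test Acc %.1f%%, CV Acc %.1f%% (cv lambdas: %s; selected: %s)",
                task, row$test_accuracy, row$cv_accuracy,
                paste(signif(cv$folds$chosen_lambda, 3), collapse = ","),
                paste(cv$folds$n_selected, collapse = ","))
    }

    stage <- "summary"
    summary <- dplyr::bind_rows(summary_rows)
    jsonlite::write_json(summary, file.path(out, "summary.json"), digits = NA)
    utils::write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
    .log_line(log_path, "pipeline done")
    structure(
      list(summary = summary, tasks = task_results, manifest = manifest,
           out_dir = out, config = config),
      class = "fqc_run"
    )
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

.write_report_json <- function(report, path) {
  x <- list(
    confusion = report$cm[c("tp", "fp", "tn", "fn")],
    positive_class = report$cm$positive_class,
    metrics = as.list(report$metrics[, c("sensitivity", "specificity", "accuracy")]),
    auc = round(report$auc, 3),
    threshold = report$threshold
  )
  if (!is.null(report$breakdown) && nrow(report$breakdown) > 0) {
    x$breakdown <- report$breakdown
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}

#' @export
print.fqc_run <- function(x, ...) {
  cat("<fqc_run>\n")
  print(x$summary)
  invisible(x)
}
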