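#' Stratified k-fold cross-validation with in-fold selection
#'
#' Splits the samples into `k` stratified folds and, inside every training
#' fold, re-runs the whole modelling chain — column standardization,
#' elastic-net feature selection and classifier fitting — so no information
#' leaks from a held-out fold into its model. Out-of-fold probabilities are
#' pooled into a single confusion matrix, metric set and ROC/AUC.
#'
#' @param X Feature matrix/data frame.
#' @param y Labels (two classes).
#' @param k Number of folds (default 10). Each class must have at least `k`
#'   members; otherwise an error suggests a smaller `k`.
#' @param kind Classifier used inside the folds (default `"svm"`).
#' @param positive_class Label counted as positive.
#' @param alpha,n_lambda Elastic-net parameters (see [fit_elastic_net()]).
#' @param hyperparams Classifier overrides (see [train_classifier()]).
#' @param rng_seed Seed controlling fold assignment and all in-fold fits.
#' @param subtypes Optional subtype labels for the pooled misclassification
#'   breakdown.
#' @param threshold Probability cut for pooled hard labels.
#' @return An object of class `fqc_cv`: `report` (an `fqc_report` on the
#'   pooled predictions), `predictions` (tibble sample, fold, truth, prob)
#'   and `folds` (per-fold chosen lambda and selected-feature count).
#' @export
crossvalidate <- function(X, y, k = 10, kind = c("svm", "random_forest"),
                          positive_class = NULL, alpha = 0.5, n_lambda = 100,
                          hyperparams = list(), rng_seed = 1L,
                          subtypes = NULL, threshold = 0.5) {
  kind <- match.arg(kind)
  X <- .as_feature_matrix(X)
  if (is.null(positive_class)) positive_class <- sort(unique(as.character(y)))[2]
  enc <- .encode_binary(y, positive_class)
  if (min(table(enc$bin)) < k) {
    stop(sprintf(
      "smallest class has %d samples, fewer than k = %d folds; use a smaller k",
      min(table(enc$bin)), k), call. = FALSE)
  }
  foldid <- .make_folds(enc$bin, k, derive_seed(rng_seed, 1L))
  prob <- numeric(nrow(X))
  fold_rows <- list()
  for (f in seq_len(k)) {
    tr <- foldid != f
    sel <- fit_elastic_net(X[tr, , drop = FALSE], enc$bin[tr], alpha = alpha,
                           n_lambda = n_lambda,
                           cv_folds = min(10, min(table(enc$bin[tr]))),
                           rng_seed = derive_seed(rng_seed, 100L + f))
    mdl <- train_classifier(X[tr, , drop = FALSE],
                            as.character(enc$factor[tr]), sel, kind = kind,
                            hyperparams = hyperparams,
                            rng_seed = derive_seed(rng_seed, 200L + f),
                            positive_class = enc$positive,
                            negative_class = enc$negative)
    prob[!tr] <- predict_proba(mdl, X[!tr, , drop = FALSE])
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      chosen_lambda = sel$chosen_lambda,
      n_selected = nrow(sel$selected)
    )
  }
  report <- quality_report(as.character(enc$factor), prob,
                           positive_class = enc$positive,
                           negative_class = enc$negative,
                           threshold = threshold, subtypes = subtypes)
  structure(
    list(
      report = report,
      predictions = tibble::tibble(
        sample = seq_len(nrow(X)), fold = foldid,
        truth = as.character(enc$factor), prob = prob
      ),
      folds = dplyr::bind_rows(fold_rows),
      k = k, kind = kind, rng_seed = rng_seed
    ),
    class = "fqc_cv"
  )
}

#' @export
print.fqc_cv <- function(x, ...) {
  cat(sprintf("<fqc_cv> %d-fold, %s, pooled:\n", x$k, x$kind))
  print(x$report)
  invisible(x)
}

#' @rdname tidy.fqc_selection
#' @export
glance.fqc_cv <- function(x, ...) {
  dplyr::mutate(glance(x$report), k = x$k, kind = x$kind)
}

#' @rdname tidy.fqc_selection
#' @export
tidy.fqc_cv <- function(x, ...) x$folds
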