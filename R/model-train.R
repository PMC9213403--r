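#' Train a classifier on the selected features
#'
#' Fits a random forest (default: 500 trees, `sqrt(p)` candidate features per
#' split, probability = fraction of trees voting for the positive class) or
#' an RBF support vector machine (`gamma = 1/p`, `C = 1`; probabilities are a
#' logistic transform of the decision values, which keeps predictions
#' deterministic and leaves the ranking, hence the ROC, identical) on the
#' standardized selected features.
#'
#' @param X Feature matrix/data frame covering at least the selected features.
#' @param y Labels (character/factor with the task's two classes).
#' @param selection An `fqc_selection` from [fit_elastic_net()].
#' @param kind `"random_forest"` or `"svm"`.
#' @param hyperparams Named list of overrides (`ntree`, `mtry`; `gamma`,
#'   `cost`).
#' @param rng_seed Seed for the forest's bootstrap.
#' @param positive_class,negative_class Class labels; class order is fixed as
#'   (negative, positive).
#' @param decision_threshold Probability cut for hard labels (default 0.5).
#' @return An object of class `fqc_model`.
#' @export
train_classifier <- function(X, y, selection, kind = c("random_forest", "svm"),
                             hyperparams = list(), rng_seed = 1L,
                             positive_class = NULL, negative_class = NULL,
                             decision_threshold = 0.5) {
  kind <- match.arg(kind)
  if (!inherits(selection, "fqc_selection")) {
    stop_param("selection", "must be an fqc_selection")
  }
  if (nrow(selection$selected) == 0) stop("empty feature selection", call. = FALSE)
  if (is.null(positive_class)) positive_class <- selection$positive_class
  enc <- .encode_binary(y, positive_class, negative_class)
  Xs <- .apply_selection(selection, X)
  p <- ncol(Xs)

  fitted <- if (kind == "random_forest") {
    ntree <- hyperparams$ntree %||% 500
    mtry <- hyperparams$mtry %||% max(1, floor(sqrt(p)))
    with_seed(rng_seed,
              randomForest::randomForest(Xs, enc$factor, ntree = ntree, mtry = mtry))
  } else {
    gamma <- hyperparams$gamma %||% (1 / p)
    cost <- hyperparams$cost %||% 1
    with_seed(rng_seed,
              e1071::svm(Xs, enc$factor, kernel = "radial", gamma = gamma,
                         cost = cost, scale = FALSE))
  }
  structure(
    list(
      kind = kind,
      fitted = fitted,
      selection = selection,
      positive_class = enc$positive,
      negative_class = enc$negative,
      decision_threshold = decision_threshold,
      rng_seed = rng_seed
    ),
    class = "fqc_model"
  )
}

#' Predict positive-class probabilities
#'
#' @param model An `fqc_model`.
#' @param X Feature matrix/data frame containing the model's selected
#'   features (an informative error lists any missing names).
#' @return Numeric vector of probabilities of the positive class, in \[0, 1\].
#' @export
predict_proba <- function(model, X) {
  if (!inherits(model, "fqc_model")) stop_param("model", "must be an fqc_model")
  Xs <- .apply_selection(model$selection, X)
  if (model$kind == "random_forest") {
    pr <- stats::predict(model$fitted, Xs, type = "prob")
    unname(pr[, model$positive_class])
  } else {
    dv <- attr(stats::predict(model$fitted, Xs, decision.values = TRUE),
               "decision.values")
    lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
    s <- if (lab[1] == model$positive_class) 1 else -1
    unname(stats::plogis(s * dv[, 1]))
  }
}

#' Predict hard class labels
#'
#' @inheritParams predict_proba
#' @param threshold Probability threshold; defaults to the model's
#'   `decision_threshold`. Prediction is positive when probability >=
#'   threshold.
#' @return Character vector of class labels.
#' @export
predict_label <- function(model, X, threshold = NULL) {
  threshold <- threshold %||% model$decision_threshold
  pr <- predict_proba(model, X)
  ifelse(pr >= threshold, model$positive_class, model$negative_class)
}

#' @export
print.fqc_model <- function(x, ...) {
  cat(sprintf("<fqc_model> %s on %d selected features (positive = %s)\n",
              x$kind, nrow(x$selection$selected), x$positive_class))
  invisible(x)
}

#' @rdname tidy.fqc_selection
#' @export
glance.fqc_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_selected = nrow(x$selection$selected),
    positive_class = x$positive_class,
    negative_class = x$negative_class,
    decision_threshold = x$decision_threshold
  )
}
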