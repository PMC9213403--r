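.as_feature_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- as.matrix(X[vapply(X, is.numeric, logical(1))])
  }
  if (!is.matrix(X)) stop_param("X", "must be a numeric matrix or data frame")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  X
}

.encode_binary <- function(y, positive_class, negative_class = NULL) {
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("y must contain both classes", call. = FALSE)
  if (length(classes) > 2) stop("y must be binary", call. = FALSE)
  if (is.null(negative_class)) negative_class <- setdiff(classes, positive_class)
  if (!positive_class %in% classes || !negative_class %in% classes) {
    stop_param("positive_class", "not found among the labels of y")
  }
  list(bin = as.integer(y == positive_class),
       factor = factor(y, levels = c(negative_class, positive_class)),
       positive = positive_class, negative = negative_class)
}

# stratified fold assignment, seeded
.make_folds <- function(y_bin, k, seed) {
  foldid <- integer(length(y_bin))
  with_seed(seed, {
    for (cl in unique(y_bin)) {
      idx <- which(y_bin == cl)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Elastic-net penalized-likelihood feature selection
#'
#' Fits the regularization path of a penalized binomial log-likelihood with
#' mixing parameter `alpha` (glmnet), chooses the penalty by cross-validated
#' deviance, and reports the features with nonzero coefficients at that
#' penalty. The default `lambda_rule = "1se"` takes the largest penalty whose
#' mean CV deviance is within one standard error of the minimum; the raw
#' minimum (`"min"`) chases fold noise on label-free data and admits spurious
#' features, so the parsimonious rule is the default (see the methods
#' vignette for the calibration evidence). Columns are standardized internally (zero
#' mean, unit variance; constant columns are dropped with a warning) and the
#' standardization statistics are stored so downstream classifiers can apply
#' them to new data without leakage.
#'
#' If no coefficient is nonzero at the chosen penalty (which can happen when
#' the labels carry no signal), the selection falls back to the largest
#' penalty at which at least one feature enters, so the selected set is never
#' empty.
#'
#' @param X Numeric feature matrix (or data frame of numerics), one row per
#'   sample, named columns.
#' @param y Binary labels: 0/1, logical, or a two-level factor/character
#'   (1 / the `positive_class` is the positive).
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param n_lambda Length of the penalty grid (default 100).
#' @param cv_folds Folds for the internal deviance cross-validation
#'   (default 10).
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param rng_seed Seed for the fold assignment.
#' @param positive_class For character/factor `y`, which level codes 1.
#' @return An object of class `fqc_selection`: `lambda_grid`, `coef_path`
#'   (features x lambda sparse matrix), `chosen_lambda`, `selected` (tibble of
#'   index, feature, coefficient), `standardization`, `cv_deviance`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, n_lambda = 100, cv_folds = 10,
                            rng_seed = 1L, positive_class = NULL,
                            lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- .as_feature_matrix(X)
  if (is.numeric(y) || is.logical(y)) {
    y_bin <- as.integer(y)
    if (!all(y_bin %in% c(0L, 1L))) stop_param("y", "numeric y must be 0/1")
    enc <- list(positive = "1", negative = "0")
  } else {
    if (is.null(positive_class)) positive_class <- sort(unique(as.character(y)))[2]
    enc <- .encode_binary(y, positive_class)
    y_bin <- enc$bin
  }
  if (length(unique(y_bin)) < 2) stop("y contains a single class", call. = FALSE)
  if (nrow(X) < cv_folds) stop("fewer samples than cv_folds", call. = FALSE)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(!keep)))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")

  foldid <- .make_folds(y_bin, cv_folds, rng_seed)
  cv <- glmnet::cv.glmnet(Xs, y_bin, family = "binomial", alpha = alpha,
                          nlambda = n_lambda, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  fit <- cv$glmnet.fit
  chosen <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.matrix(stats::coef(fit, s = chosen))[-1, 1]
  if (!any(beta != 0)) {
    nz <- which(fit$df >= 1)
    if (length(nz) > 0) {
      chosen <- fit$lambda[nz[1]]
      beta <- as.matrix(stats::coef(fit, s = chosen))[-1, 1]
    }
  }
  sel_idx <- which(beta != 0)
  selected <- tibble::tibble(
    index = match(names(beta)[sel_idx], colnames(X)),
    feature = names(beta)[sel_idx],
    coefficient = unname(beta[sel_idx])
  )
  structure(
    list(
      lambda_grid = fit$lambda,
      coef_path = fit$beta,
      chosen_lambda = chosen,
      selected = selected,
      alpha = alpha,
      cv_deviance = tibble::tibble(lambda = cv$lambda, mean_deviance = cv$cvm,
                                   se = cv$cvsd),
      standardization = list(mean = mu, sd = sdv, kept = colnames(X)[keep]),
      positive_class = enc$positive,
      negative_class = enc$negative,
      rng_seed = rng_seed
    ),
    class = "fqc_selection"
  )
}

#' @export
print.fqc_selection <- function(x, ...) {
  cat(sprintf(
    "<fqc_selection> %d/%d features selected at lambda = %.5g (alpha = %.2f)\n",
    nrow(x$selected), length(x$standardization$mean), x$chosen_lambda, x$alpha))
  invisible(x)
}

#' Tidy an elastic-net selection
#'
#' @param x An `fqc_selection` from [fit_elastic_net()].
#' @param ... Unused.
#' @return A tibble with one row per selected feature: `index`, `feature`,
#'   `coefficient`.
#' @export
tidy.fqc_selection <- function(x, ...) x$selected

#' @rdname tidy.fqc_selection
#' @return For `glance()`: a one-row tibble summarizing the fit.
#' @export
glance.fqc_selection <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$standardization$mean),
    n_selected = nrow(x$selected),
    chosen_lambda = x$chosen_lambda,
    alpha = x$alpha,
    min_cv_deviance = min(x$cv_deviance$mean_deviance)
  )
}

# standardize new data with stored statistics, restricted to selected features
.apply_selection <- function(selection, X) {
  X <- .as_feature_matrix(X)
  need <- selection$selected$feature
  miss <- setdiff(need, colnames(X))
  if (length(miss) > 0) {
    stop(sprintf("missing feature column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  st <- selection$standardization
  Xs <- X[, need, drop = FALSE]
  sweep(sweep(Xs, 2, st$mean[need]), 2, st$sd[need], "/")
}
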