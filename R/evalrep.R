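#' Confusion matrix for a binary task
#'
#' @param y_true,y_pred Equal-length label vectors drawn from the task's two
#'   classes (an unknown label is an error).
#' @param positive_class The label counted as positive.
#' @param negative_class The label counted as negative; inferred when the
#'   vocabulary has exactly two labels.
#' @return An object of class `fqc_confusion` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred, positive_class, negative_class = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  vocab <- unique(c(y_true, y_pred))
  if (is.null(negative_class)) {
    negative_class <- setdiff(vocab, positive_class)
    if (length(negative_class) != 1) {
      stop("negative_class cannot be inferred; pass it explicitly", call. = FALSE)
    }
  }
  unknown <- setdiff(vocab, c(positive_class, negative_class))
  if (length(unknown) > 0) {
    stop(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true == negative_class & y_pred == positive_class)
  tn <- sum(y_true == negative_class & y_pred == negative_class)
  fn <- sum(y_true == positive_class & y_pred == negative_class)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         positive_class = positive_class, negative_class = negative_class),
    class = "fqc_confusion"
  )
}

#' @export
print.fqc_confusion <- function(x, ...) {
  cat(sprintf("<fqc_confusion> positive = %s\n", x$positive_class))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive_class, x$negative_class),
                              predicted = c(x$positive_class, x$negative_class)))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' Percentages rounded to one decimal. A metric whose denominator is zero is
#' reported as `NA` (undefined), not as 0.
#'
#' @param cm An `fqc_confusion` (or a list with `tp`, `fp`, `tn`, `fn`).
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy` (in
#'   percent) plus the four counts.
#' @examples
#' qc_metrics(confusion(c("a", "a", "b"), c("a", "b", "b"), "a"))
#' @export
qc_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  tibble::tibble(
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + fp + tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' ROC curve and AUC
#'
#' Sweeps every observed score as a threshold (prediction is positive when
#' score >= threshold), returns the resulting (FPR, TPR) points and the
#' trapezoidal area under the curve. The trapezoidal AUC equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted one half.
#'
#' @param y_true Label vector.
#' @param scores Numeric scores, larger = more positive.
#' @param positive_class Label counted as positive.
#' @return An object of class `fqc_roc`: `points` (tibble threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_auc <- function(y_true, scores, positive_class) {
  y_true <- as.character(y_true)
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  pos <- y_true == positive_class
  if (!any(pos) || all(pos)) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(pos); nn <- sum(!pos)
  tpr <- vapply(th, function(t) sum(scores >= t & pos) / np, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !pos) / nn, numeric(1))
  pts <- tibble::tibble(
    threshold = c(Inf, th, -Inf),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive_class = positive_class),
            class = "fqc_roc")
}

#' @export
print.fqc_roc <- function(x, ...) {
  cat(sprintf("<fqc_roc> %d points, AUC = %.3f (positive = %s)\n",
              nrow(x$points), x$auc, x$positive_class))
  invisible(x)
}

#' ROC curve plot
#'
#' @param object An `fqc_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fqc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

# round shares (in percent, 1 decimal) so they sum exactly to 100.0
.largest_remainder_pct <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(numeric(0))
  raw <- 1000 * counts / tot  # tenths of a percent
  base <- floor(raw)
  left <- 1000L - sum(base)
  if (left > 0) {
    ord <- order(raw - base, counts, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  base / 10
}

#' Misclassification breakdown by subtype
#'
#' Tabulates, separately for false positives and false negatives, the
#' subtype composition of the misclassified samples (e.g. which eye
#' abnormalities ended up classified as artefacts), with percent shares
#' rounded by largest remainder so each direction sums to exactly 100.0.
#'
#' @param y_true,y_pred Label vectors for a binary task.
#' @param subtypes Per-sample subtype labels (e.g. abnormality kind or
#'   artefact kind); `NA` is bucketed as `"unspecified"`.
#' @param positive_class Label counted as positive.
#' @param negative_class Optional explicit negative label.
#' @return A tibble with columns `direction` (`false_positive` /
#'   `false_negative`), `subtype`, `n`, `share_pct`.
#' @export
misclassification_breakdown <- function(y_true, y_pred, subtypes,
                                        positive_class, negative_class = NULL) {
  cm <- confusion(y_true, y_pred, positive_class, negative_class)  # validates
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  subtypes <- as.character(subtypes)
  subtypes[is.na(subtypes)] <- "unspecified"
  out <- list()
  for (dir in c("false_positive", "false_negative")) {
    sel <- if (dir == "false_positive") {
      y_pred == cm$positive_class & y_true == cm$negative_class
    } else {
      y_pred == cm$negative_class & y_true == cm$positive_class
    }
    if (!any(sel)) next
    tab <- sort(table(subtypes[sel]), decreasing = TRUE)
    out[[dir]] <- tibble::tibble(
      direction = dir,
      subtype = names(tab),
      n = as.integer(tab),
      share_pct = .largest_remainder_pct(as.integer(tab))
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(direction = character(0), subtype = character(0),
                          n = integer(0), share_pct = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Full evaluation report for one prediction set
#'
#' Bundles the confusion matrix, sensitivity/specificity/accuracy, the ROC
#' curve with its AUC, and (when subtypes are supplied) the
#' misclassification breakdown.
#'
#' @param y_true True labels.
#' @param prob Predicted positive-class probabilities.
#' @param positive_class,negative_class Task classes.
#' @param threshold Probability cut for hard labels (default 0.5; prediction
#'   is positive when prob >= threshold).
#' @param subtypes Optional per-sample subtype labels for the breakdown.
#' @return An object of class `fqc_report`.
#' @export
quality_report <- function(y_true, prob, positive_class, negative_class = NULL,
                           threshold = 0.5, subtypes = NULL) {
  y_true <- as.character(y_true)
  if (is.null(negative_class)) {
    negative_class <- setdiff(unique(y_true), positive_class)
    if (length(negative_class) != 1) {
      stop("negative_class cannot be inferred; pass it explicitly", call. = FALSE)
    }
  }
  y_pred <- ifelse(prob >= threshold, positive_class, negative_class)
  cm <- confusion(y_true, y_pred, positive_class, negative_class)
  roc <- roc_auc(y_true, prob, positive_class)
  breakdown <- if (!is.null(subtypes)) {
    misclassification_breakdown(y_true, y_pred, subtypes, positive_class,
                                negative_class)
  } else NULL
  structure(
    list(cm = cm, metrics = qc_metrics(cm), roc = roc,
         auc = roc$auc, breakdown = breakdown, threshold = threshold),
    class = "fqc_report"
  )
}

#' @export
print.fqc_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<fqc_report> Se %.1f%%  Sp %.1f%%  Acc %.1f%%  AUC %.3f  (n = %d)\n",
    m$sensitivity, m$specificity, m$accuracy, x$auc,
    m$tp + m$fp + m$tn + m$fn))
  invisible(x)
}

#' @rdname tidy.fqc_selection
#' @export
glance.fqc_report <- function(x, ...) {
  dplyr::mutate(x$metrics, auc = round(x$auc, 3), .before = "tp")
}
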