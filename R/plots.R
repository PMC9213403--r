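#' Display a synthetic fundus image
#'
#' @param object A `fundus_image`.
#' @param ... Unused.
#' @return A ggplot showing the RGB raster.
#' @export
autoplot.fundus_image <- function(object, ...) {
  px <- object$pixels / 255
  h <- dim(px)[1]; w <- dim(px)[2]
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$fill <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(
      title = sprintf("label: %s%s", object$label,
                      if (object$poor_subtype != "none") {
                        paste0(" (", object$poor_subtype, ")")
                      } else ""),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' Out-of-fold probability distributions of a cross-validation
#'
#' Violin plot of pooled out-of-fold positive-class probabilities by true
#' class — the standard visual check that the two classes separate along the
#' probability axis.
#'
#' @param object An `fqc_cv` from [crossvalidate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fqc_cv <- function(object, ...) {
  df <- object$predictions
  pos <- object$report$cm$positive_class
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$prob)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$report$threshold, linetype = 2) +
    ggplot2::labs(
      x = "true class",
      y = sprintf("out-of-fold P(%s)", pos),
      title = sprintf("%d-fold CV, pooled accuracy %.1f%%",
                      object$k, object$report$metrics$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Misclassification-breakdown bar chart
#'
#' @param breakdown A tibble from [misclassification_breakdown()].
#' @return A ggplot of counts per subtype, faceted by error direction.
#' @export
plot_breakdown <- function(breakdown) {
  ggplot2::ggplot(breakdown,
                  ggplot2::aes(x = stats::reorder(.data$subtype, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$share_pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~.data$direction, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "misclassified images") +
    ggplot2::theme_minimal()
}
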