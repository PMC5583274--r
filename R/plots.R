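# ggplot2 autoplot methods for the main result types.

#' @export
autoplot.concurrency_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$n)) +
    ggplot2::geom_col(width = diff(c(object$bin_start[1], object$bin_end[1])),
                      fill = "grey35") +
    ggplot2::labs(x = "Retention time (min)", y = "Transitions per bin",
                  title = "Scheduled-MRM concurrency profile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.precision_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_analyte[object$per_analyte$flag == "ok", ],
    cols = c("cv_intra", "cv_inter", "cv_total"),
    names_to = "metric", values_to = "cv"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$cv)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "CV (%)",
                  title = "Per-analyte precision components") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.linearity_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_analyte, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0.9, linetype = 2) +
    ggplot2::labs(x = "Pearson r (area vs mix fraction)", y = "Analytes",
                  title = "Admixture linearity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.carryover_summary <- function(object, ...) {
  d <- object$per_analyte[object$per_analyte$flag == "ok", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$carryover_pct)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(2, 4), linetype = 2) +
    ggplot2::labs(x = "Carryover (% of ULOQ)", y = "Analytes",
                  title = "Carryover distribution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tube_comparison <- function(object, ...) {
  d <- object$per_analyte[!object$per_analyte$censored, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(.data$p_adj))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~tube) +
    ggplot2::labs(
      x = sprintf("log2 fold change vs %s", object$reference_tube),
      y = "-log10 adjusted p", title = "Collection-tube effects"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plsda <- function(object, data = NULL, y = NULL, ...) {
  d <- augment(object)
  if (!is.null(y)) d$group <- as.character(y)
  if (object$n_components >= 2) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.comp1, y = .data$.comp2))
  } else {
    d$jitter <- 0
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.comp1, y = .data$jitter))
  }
  if (!is.null(y)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "Component 1", y = "Component 2",
                    title = "PLS-DA scores") +
    ggplot2::theme_minimal()
}

#' ROC curve coordinates for a score vector
#'
#' @param scores Per-sample risk scores.
#' @param y Binary labels (second level = case).
#' @return A tibble of `fpr`, `tpr` stepping through score thresholds.
#' @export
roc_coordinates <- function(scores, y) {
  cls <- .binary_labels(y)
  ord <- order(scores, decreasing = TRUE)
  y_sorted <- cls$y01[ord]
  tibble(
    fpr = c(0, cumsum(y_sorted == 0) / sum(y_sorted == 0)),
    tpr = c(0, cumsum(y_sorted == 1) / sum(y_sorted == 1))
  )
}

#' @export
autoplot.classifier_report <- function(object, ...) {
  d <- tibble(auroc = object$rdcv_aurocs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$auroc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$auroc, colour = "red") +
    ggplot2::labs(
      x = "Held-out AUROC",
      y = "Outer folds",
      title = sprintf("rdCV AUROC distribution (full-cohort AUROC %.2f)",
                      object$auroc)
    ) +
    ggplot2::theme_minimal()
}
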