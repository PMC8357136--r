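#' Plot the distribution of resampled evaluation metrics
#'
#' For regression, a histogram of per-iteration R-squared values with the
#' mean and the 95% percentile interval marked; for classification, a
#' histogram of per-iteration accuracy.
#'
#' @param object An `age_eval` result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_eval <- function(object, bins = 30, ...) {
  it <- tidy(object)
  if (object$task == "regression") {
    g <- glance(object)
    ggplot2::ggplot(it, ggplot2::aes(x = .data$r2)) +
      ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
      ggplot2::geom_vline(xintercept = g$mean_r2, linetype = 1) +
      ggplot2::geom_vline(xintercept = c(g$r2_ci_low, g$r2_ci_high), linetype = 2) +
      ggplot2::labs(x = expression(R^2~"on held-out samples"), y = "iterations",
                    title = sprintf("Resampled age regression (%d features)",
                                    object$n_features))
  } else {
    ggplot2::ggplot(it, ggplot2::aes(x = .data$accuracy)) +
      ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
      ggplot2::labs(x = "held-out accuracy", y = "iterations",
                    title = sprintf("Resampled age-group classification (%d features)",
                                    object$n_features))
  }
}

#' Plot a mean confusion matrix
#'
#' Heat-tile view of the iteration-averaged 3x3 confusion matrix of an
#' age-group classification run (rows = true group).
#'
#' @param eval An `age_eval` from [evaluate_classification()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(eval) {
  stopifnot(inherits(eval, "age_eval"), eval$task == "classification")
  df <- as_tibble(as.table(eval$confusion))
  names(df) <- c("true", "predicted", "mean_count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$mean_count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$mean_count))) +
    ggplot2::scale_y_discrete(limits = rev(rownames(eval$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "predicted group", y = "true group",
                  fill = "mean\ncount",
                  title = "Mean confusion matrix over resampling iterations")
}

#' Plot per-study log-expression distributions
#'
#' Density of normalized log expression by study — separated curves mean a
#' residual study effect; good normalization pulls them together.
#'
#' @param nm A [log_cpm()] result.
#' @return A ggplot object.
#' @export
plot_study_densities <- function(nm) {
  stopifnot(inherits(nm, "normalized_matrix"))
  df <- as_tibble(nm) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "log_expr") |>
    left_join(nm$samples[c("sample_id", "study_id")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_expr, colour = .data$study_id)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log2 CPM", colour = "study",
                  title = sprintf("Per-study expression distributions (%s)", nm$method))
}

#' Plot the age-correlation profile of ranked genes
#'
#' Histogram of per-gene correlation with age; planted or selected genes
#' can be highlighted by passing their ids.
#'
#' @param object An [correlate_with_age()] table.
#' @param highlight Optional gene ids drawn as a rug.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_correlation <- function(object, highlight = NULL, bins = 50, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", colour = "white") +
    ggplot2::labs(x = "Pearson r with age", y = "genes",
                  title = "Gene-age correlation distribution")
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_rug(data = object[object$gene_id %in% highlight, ],
                               colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
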