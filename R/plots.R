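#' Plot the ferroptosis/apoptosis landscape
#'
#' @param landscape Tibble from [landscape_scores()].
#' @return A ggplot object: one labelled point per treatment on the
#'   ferroptosis (x) vs apoptosis (y) enrichment plane.
#' @export
plot_landscape <- function(landscape) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$ferro, y = .data$apopt,
                               label = .data$treatment)) +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(x = "Ferroptosis signature enrichment",
                  y = "Apoptosis signature enrichment",
                  title = "Cell-death landscape") +
    ggplot2::theme_minimal()
}

#' Plot per-class enrichment scores of a classification report
#'
#' @param object A `classification_report` from [evaluate_signature()].
#' @param ... Unused.
#' @return A ggplot: jittered per-dataset scores by class with the class
#'   median, annotated with the ROC-AUC.
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$class, y = .data$score,
                               colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "black", linewidth = 0.3) +
    ggplot2::labs(y = "ssGSEA score", x = NULL,
                  subtitle = sprintf("ROC-AUC = %.2f", object$auc)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for one or two patient groups
#'
#' @param times,events Survival data as in [km_estimate()].
#' @param groups Optional grouping vector; one curve per group.
#' @return A ggplot step plot of survival probability over time.
#' @export
plot_km <- function(times, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(times))
  km <- dplyr::bind_rows(lapply(split(seq_along(times), groups), function(i) {
    est <- km_estimate(times[i], events[i])
    dplyr::bind_rows(tibble::tibble(time = 0, n_risk = length(i),
                                    n_event = 0, n_censor = 0, surv = 1),
                     est)
  }), .id = "group")
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap selection frequencies of the datasets-derived ranking
#'
#' @param ranked Tibble from [rank_datasets_derived()].
#' @param top_n Number of top genes to display (default 25).
#' @return A ggplot bar chart of selection frequency for the top genes.
#' @export
plot_selection_frequency <- function(ranked, top_n = 25) {
  d <- utils::head(ranked, top_n)
  d$gene <- factor(d$gene, levels = rev(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sel_freq, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Bootstrap selection frequency", y = NULL) +
    ggplot2::theme_minimal()
}
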