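# ggplot2 displays for fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Loss trace of an IBDS run
#'
#' Current and best-so-far loss against iteration, with the selector used
#' at each iteration mapped to point shape.
#'
#' @param object An `ibds_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibds_fit <- function(object, ...) {
  log <- object$log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss, colour = "current")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_loss, colour = "best")) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$loss, shape = .data$method),
      data = log[log$method == "MAR", ], size = 1.6
    ) +
    ggplot2::scale_colour_manual(
      values = c(current = "grey40", best = "#B2182B"), name = NULL
    ) +
    ggplot2::labs(x = "Iteration", y = "Loss",
                  title = "IBDS loss trace", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Weight distribution of an IBDS run
#'
#' Histogram of the final protein weights on a log10 axis, with the
#' candidate threshold marked; known AD proteins are shown in their own
#' fill.
#'
#' @param fit An `ibds_fit`.
#' @param bins Number of histogram bins. Default 60.
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(fit, bins = 60) {
  stopifnot(inherits(fit, "ibds_fit"))
  d <- tidy(fit)
  d <- d[d$weight > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight, fill = .data$known)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.8, position = "stack") +
    ggplot2::geom_vline(xintercept = fit$config$candidate_threshold,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Protein weight (log scale)", y = "Proteins",
                  fill = "Known AD protein",
                  title = "Final weight distribution") +
    ggplot2::theme_minimal()
}

#' Sweep summary across initial masses
#'
#' Box plots of the candidate-range weights (weights above the candidate
#' threshold) for each initial mass, annotated with the number of
#' candidates per run.
#'
#' @param object An `ibds_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibds_sweep <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$candidate, ]
  counts <- dplyr::count(d, .data$initial_mass)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$initial_mass),
                                  y = .data$weight)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(
      data = counts,
      ggplot2::aes(x = factor(.data$initial_mass), y = max(d$weight) * 1.1,
                   label = .data$n),
      size = 3
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Initial mass on known proteins",
                  y = "Candidate weights (log scale)",
                  title = "Candidates across initial values") +
    ggplot2::theme_minimal()
}

#' Per-fold AUCs of a cross-validation report
#'
#' @param object An `ibds_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibds_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$auc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$auc, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "grey60") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Fold", y = "AUC",
                  title = "Positive-unlabeled cross-validation") +
    ggplot2::theme_minimal()
}
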