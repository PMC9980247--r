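# ggplot2 displays for the two experiment result types.

#' Plot train-vs-test AUC pairs from a shuffle-split experiment
#'
#' One point per split; the dashed identity diagonal marks perfect
#' generalization. An anti-diagonal cloud (points sliding from
#' below-diagonal to above-diagonal) is the train/test tradeoff signature;
#' flagged splits (covariate imbalance) are drawn solid.
#'
#' @param object A [run_split_experiment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.split_experiment <- function(object, ...) {
  d <- object$splits
  ggplot2::ggplot(d, ggplot2::aes(x = .data$train_auc, y = .data$test_auc,
                                  colour = .data$model_type,
                                  shape = .data$family,
                                  alpha = .data$balance_flag)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.45, `TRUE` = 1),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Training AUC (mean CV validation)",
                  y = "Test AUC", colour = "Model", shape = "Classifier") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.split_experiment
#' @export
plot.split_experiment <- function(x, ...) print(autoplot.split_experiment(x, ...))

#' Plot a learning curve as per-size boxplots
#'
#' Boxplots of cross-validated AUC across chains at each cohort size, with
#' the estimated convergence size marked by a vertical line.
#'
#' @param object A [run_learning_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_curve <- function(object, ...) {
  d <- object$curve
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$size),
                                       y = .data$cv_auc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "Number of cases", y = "Cross-validated AUC") +
    ggplot2::theme_minimal()
  if (!is.na(object$convergence_size)) {
    lvl <- match(object$convergence_size, sort(unique(d$size)))
    p <- p + ggplot2::geom_vline(xintercept = lvl, linetype = "dotted",
                                 colour = "firebrick")
  }
  p
}

#' @rdname autoplot.learning_curve
#' @export
plot.learning_curve <- function(x, ...) print(autoplot.learning_curve(x, ...))
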