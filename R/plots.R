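#' Plot methods
#'
#' `autoplot()` methods render the package's result objects with ggplot2:
#' simulated traces with stimulation marks and detected seizure onset,
#' input-output curves, NMF sub-network weights, classifier permutation
#' nulls, and time-resolved accuracy traces with their chance band.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name epiprobe-plots
NULL

#' @rdname epiprobe-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.epileptor_sim <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$t_ms / 1000,
                                        y = .data$ieeg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "iEEG proxy",
                  title = paste0("Epileptor simulation (x0 = ",
                                 object$params$x0, ")"))
  if (any(tr$stim > 0))
    p <- p + ggplot2::geom_rug(data = tr[tr$stim > 0, ],
                               sides = "b", colour = "steelblue",
                               alpha = 0.5)
  if (!is.na(object$seizure_onset_ms))
    p <- p + ggplot2::geom_vline(xintercept = object$seizure_onset_ms / 1000,
                                 colour = "red", linetype = 2)
  p
}

#' @rdname epiprobe-plots
#' @export
autoplot.ioc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$intensity, y = .data$response)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "stimulation intensity (normalised)",
                  y = "normalised response",
                  title = sprintf("Input-output curve (IOC = %.3f)",
                                  attr(object, "ioc")))
}

#' @rdname epiprobe-plots
#' @export
autoplot.nmf_decomposition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = factor(.data$component),
                               y = .data$channel, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "sub-network", y = "channel",
                  title = paste0("NMF weights (rank ", object$rank, ")"))
}

#' @rdname epiprobe-plots
#' @export
autoplot.classifier_report <- function(object, ...) {
  if (is.null(object$permutation)) {
    df <- tibble::tibble(fold = seq_along(object$fold_accuracy),
                         accuracy = object$fold_accuracy)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$fold, .data$accuracy)) +
             ggplot2::geom_col() +
             ggplot2::labs(title = paste("Fold accuracies,", object$kind)))
  }
  nulls <- tibble::tibble(score = object$permutation$null_scores)
  ggplot2::ggplot(nulls, ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$permutation$true_score,
                        colour = "red") +
    ggplot2::labs(x = "accuracy", y = "permutations",
                  title = sprintf("%s classifier: %.2f (p = %.3g)",
                                  object$kind, object$mean_accuracy,
                                  object$permutation$p_value))
}

#' @rdname epiprobe-plots
#' @export
autoplot.accuracy_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$accuracy))
  if (!all(is.na(object$chance_lo)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$chance_lo,
                                               ymax = .data$chance_hi),
                                  fill = "grey80")
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from pulse (ms)", y = "accuracy",
                  title = "Time-resolved decoding")
}

#' Plot the fast-subsystem bifurcation diagram
#'
#' S-shaped diagram of fast-subsystem equilibria against the slow
#' permittivity variable, with stability coding and the fold point marked.
#'
#' @param diagram output of [bifurcation_diagram()].
#' @return A ggplot object.
#' @export
plot_bifurcation <- function(diagram) {
  fold <- attr(diagram, "fold")
  ggplot2::ggplot(diagram, ggplot2::aes(.data$z, .data$x1,
                                        linetype = .data$stable,
                                        group = interaction(.data$branch,
                                                            .data$stable))) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::annotate("point", x = fold["z"], y = fold["x1"], shape = 21,
                      colour = "red", size = 3) +
    ggplot2::labs(x = "permittivity z", y = "x1",
                  title = "Fast-subsystem fold bifurcation")
}
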