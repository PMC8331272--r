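#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted registration network
#'
#' @param x A `bfcnm_fit` from [train_bfcnm()].
#' @param ... Unused.
#' @return A tibble with one row per optimizer step: `iteration`, `epoch`,
#'   `pair`, `total`, `l_image`, `r1`, `r2`, `elapsed`.
#' @export
tidy.bfcnm_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted registration network
#'
#' @param x A `bfcnm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: iterations, epochs, initial/final total loss,
#'   final loss components, and parameter count.
#' @export
glance.bfcnm_fit <- function(x, ...) {
  h <- x$history
  n <- nrow(h)
  tibble::tibble(
    iterations = n,
    epochs = if (n) max(h$epoch) else 0L,
    initial_loss = if (n) h$total[1] else NA_real_,
    final_loss = if (n) h$total[n] else NA_real_,
    final_l_image = if (n) h$l_image[n] else NA_real_,
    final_r1 = if (n) h$r1[n] else NA_real_,
    final_r2 = if (n) h$r2[n] else NA_real_,
    n_parameters = n_parameters(x$network)
  )
}

#' Tidy an uncertainty threshold sweep into long format
#'
#' @param x An `uncertainty_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A tibble with columns `threshold`, `metric`
#'   (npv / tpr / ua) and `value`.
#' @export
tidy.uncertainty_sweep <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("threshold", "npv", "tpr", "ua")],
                      cols = c("npv", "tpr", "ua"),
                      names_to = "metric", values_to = "value")
}

#' Plot NPV/TPR/UA against the uncertainty threshold
#'
#' @param object An `uncertainty_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.uncertainty_sweep <- function(object, ...) {
  long <- tidy.uncertainty_sweep(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "uncertainty threshold T", y = "metric value",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object A `bfcnm_fit`.
#' @param ... Unused.
#' @return A ggplot of the total loss and its components per iteration.
#' @export
autoplot.bfcnm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history[, c("iteration", "total",
                                                 "l_image", "r1", "r2")],
                              cols = c("total", "l_image", "r1", "r2"),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss term", colour = NULL) +
    ggplot2::theme_minimal()
}
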