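#' Plot a psychometric fit
#'
#' Observed right-choice proportions per stimulus with the fitted
#' lapse-rate logistic overlaid; the dashed vertical line marks the fitted
#' subjective boundary.
#'
#' @param object An `fc_psychometric`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_psychometric <- function(object, ...) {
  counts <- object$counts
  grid <- tibble::tibble(x = seq(min(counts$x), max(counts$x),
                                 length.out = 200))
  grid$p <- psy_fun(grid$x, object$lapse_low, object$lapse_high,
                    object$threshold, object$slope)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_right / .data$n_total,
                                     size = .data$n_total)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    {if (is.finite(object$threshold))
      ggplot2::geom_vline(xintercept = object$threshold, linetype = 2)} +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "log spatial frequency (log c/deg)",
                  y = "P(right choice)") +
    ggplot2::theme_minimal()
}

#' Plot a reversal-dynamics fit
#'
#' Post-switch correct rate for the reversing stimulus with the fitted
#' exponential; the crossing of the 50% line (when defined) is the number
#' of trials to reverse choice.
#'
#' @param object An `fc_reversal`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_reversal <- function(object, ...) {
  curve <- object$curve
  grid <- tibble::tibble(n = seq(0, max(curve$n), length.out = 200))
  grid$f <- object$A * (1 - exp(-grid$n / object$tau)) + object$I
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$correct_rate)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$f)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "reversing-stimulus trial after switch",
                  y = "correct rate") +
    ggplot2::theme_minimal()
  if (object$crossing_defined) {
    p <- p + ggplot2::geom_vline(xintercept = object$n_reverse, linetype = 2)
  }
  p
}

#' Plot the parameter distribution of a cross-validated fit
#'
#' Box plots of the (run, fold) training-fit distribution for each free
#' parameter, with the reported median marked.
#'
#' @param object An `fc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_fit <- function(object, ...) {
  free <- object$variant$free
  long <- object$param_samples |>
    dplyr::select(dplyr::all_of(free)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "value")
  med <- tibble::tibble(term = free,
                        value = unname(object$median_params[free]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_point(data = med, color = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "parameter value",
                  title = paste("variant", object$variant$id)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery report
#'
#' Original versus recovered parameter values; the identity line marks
#' perfect recovery.
#'
#' @param object An `fc_recovery`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_recovery <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$original, y = .data$recovered,
                               color = .data$parameter)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "original", y = "recovered") +
    ggplot2::theme_minimal()
}

#' Latent decision-criterion trace of a simulated session
#'
#' Plots the stored criterion trajectory of a simulated dynamic-DC agent
#' with block boundaries marked.
#'
#' @param trials A simulated `fc_trials` table carrying a `latent`
#'   attribute with a `dc` column.
#' @param max_trials Optional cap on the number of trials drawn.
#' @return A ggplot object.
#' @export
plot_dc_trace <- function(trials, max_trials = NULL) {
  latent <- attr(trials, "latent")
  if (is.null(latent) || is.null(latent$dc)) {
    stop("trials carry no dynamic-criterion latent trace", call. = FALSE)
  }
  d <- dplyr::mutate(trials, t = dplyr::row_number(), dc = latent$dc)
  if (!is.null(max_trials)) d <- dplyr::slice_head(d, n = max_trials)
  switches <- d$t[d$trial_in_block == 0L & d$block_index > 0L]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$dc)) +
    ggplot2::geom_vline(xintercept = switches, color = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "decision criterion") +
    ggplot2::theme_minimal()
}
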