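#' Per-stimulus right-choice counts for psychometric fitting
#'
#' Aggregates right-choice counts per stimulus on a log-frequency axis,
#' excluding every trial within `exclude_after_switch` trials after a
#' boundary switch (the psychometric analysis uses steady-state trials
#' only). Optionally restricted by block type.
#'
#' @param trials A trial tibble.
#' @param block_type Optional `"low"` / `"high"` restriction.
#' @param exclude_after_switch Number of post-switch trials dropped from
#'   every block after the first of a session (default 30).
#' @return Tibble with `x` (log spatial frequency), `sf`, `n_right`,
#'   `n_total`.
#' @export
psychometric_counts <- function(trials, block_type = NULL,
                                exclude_after_switch = 30L) {
  keep <- trials |>
    dplyr::filter(.data$block_index == 0L |
                    .data$trial_in_block >= exclude_after_switch)
  if (!is.null(block_type)) {
    keep <- dplyr::filter(keep, .data$block_type == !!check_block_type(block_type))
  }
  keep |>
    dplyr::group_by(sf = .data$sf) |>
    dplyr::summarise(n_right = sum(.data$choice == "right"),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(x = log(.data$sf)) |>
    dplyr::select("x", "sf", "n_right", "n_total") |>
    dplyr::arrange(.data$x)
}

# 4-parameter psychometric curve: lower/upper lapse, threshold, slope
psy_fun <- function(x, lapse_low, lapse_high, threshold, slope) {
  lapse_low + (1 - lapse_low - lapse_high) /
    (1 + exp(-(x - threshold) / slope))
}

#' Fit a lapse-rate psychometric function
#'
#' Binomial maximum-likelihood fit of
#' `P(right | x) = lapse_low + (1 - lapse_low - lapse_high) /
#' (1 + exp(-(x - threshold)/slope))` on a log-frequency axis. The fitted
#' `threshold` is the subjective category boundary (in log-SF units);
#' `slope` is the inverse steepness; the two lapse parameters are the lower
#' and upper asymptote offsets, bounded to \[0, 0.5\].
#'
#' @param counts Tibble from [psychometric_counts()] (columns `x`,
#'   `n_right`, `n_total`; at least 4 distinct `x`).
#' @return An object of class `fc_psychometric`: list with `lapse_low`,
#'   `lapse_high`, `threshold`, `slope`, `nll`, `degenerate` (TRUE when the
#'   responses are all-left or all-right, in which case the boundary is not
#'   identified), and `counts`.
#' @export
fit_psychometric <- function(counts) {
  stopifnot(all(c("x", "n_right", "n_total") %in% names(counts)),
            all(counts$n_total > 0))
  if (length(unique(counts$x)) < 4) {
    stop("need >= 4 distinct stimulus values", call. = FALSE)
  }
  tot_r <- sum(counts$n_right)
  degenerate <- tot_r == 0 || tot_r == sum(counts$n_total)
  nll <- function(th) {
    p <- psy_fun(counts$x, th[1], th[2], th[3], th[4])
    p <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
    -sum(counts$n_right * log(p) +
           (counts$n_total - counts$n_right) * log(1 - p))
  }
  xr <- range(counts$x)
  span <- diff(xr)
  starts <- list(
    c(0.02, 0.02, mean(xr), span / 8),
    c(0.1, 0.1, mean(xr), span / 4),
    c(0.01, 0.01, stats::median(counts$x), span / 16)
  )
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B",
                   lower = c(0, 0, xr[1] - span, 1e-4),
                   upper = c(0.5, 0.5, xr[2] + span, 2 * span),
                   control = list(factr = 1e7)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric fit failed", call. = FALSE)
  structure(
    list(lapse_low = best$par[1], lapse_high = best$par[2],
         threshold = if (degenerate) Inf * sign(0.5 - tot_r / sum(counts$n_total))
                     else best$par[3],
         slope = best$par[4], nll = best$value,
         degenerate = degenerate, counts = counts),
    class = "fc_psychometric"
  )
}

#' @export
print.fc_psychometric <- function(x, ...) {
  cat("<fc_psychometric> threshold=", signif(x$threshold, 4),
      " (log c/deg), slope=", signif(x$slope, 3),
      ", lapses=(", signif(x$lapse_low, 3), ", ", signif(x$lapse_high, 3),
      ")", if (x$degenerate) "  [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Reversing-stimulus performance aligned to boundary switches
#'
#' Pools all switches (every block after the first of its session) and
#' computes the correct rate for the reversing stimulus at each post-switch
#' reversing-trial ordinal.
#'
#' @param trials A trial tibble.
#' @param max_trials Number of post-switch reversing-stimulus trials kept
#'   (default 60).
#' @return Tibble with `n` (1-based post-switch reversing-trial ordinal),
#'   `correct_rate`, `n_obs`.
#' @export
reversal_curve <- function(trials, max_trials = 60L) {
  rev <- trials |>
    dplyr::filter(.data$is_reversing, .data$block_index > 0L) |>
    dplyr::group_by(.data$session_id, .data$block_index) |>
    dplyr::mutate(n = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n <= max_trials)
  if (nrow(rev) == 0) stop("no post-switch reversing-stimulus trials",
                           call. = FALSE)
  rev |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(correct_rate = mean(.data$rewarded),
                     n_obs = dplyr::n(), .groups = "drop")
}

#' Exponential fit of the reversal curve and trials to reverse choice
#'
#' Least-squares fit of `f(n) = A * (1 - exp(-n / tau)) + I` to the
#' post-switch correct-rate curve of the reversing stimulus; `1 - I` is the
#' pre-switch performance and `A` the recovered gain. When the curve
#' carries an `n_obs` column the squared residuals are weighted by it, so
#' late ordinals reached by only a few switches cannot dominate the fit.
#' The number of trials to reverse choice is the analytic crossing of the
#' fitted curve through 50%: `n_reverse = -tau * log(1 - (0.5 - I) / A)`,
#' flagged as undefined when the curve never crosses 0.5.
#'
#' @param curve Tibble from [reversal_curve()] (columns `n`,
#'   `correct_rate`, optionally `n_obs`).
#' @return An object of class `fc_reversal`: list with `A`, `tau`, `I`,
#'   `n_reverse` (NA when undefined), `crossing_defined`, `curve`.
#' @export
fit_reversal <- function(curve) {
  stopifnot(all(c("n", "correct_rate") %in% names(curve)), nrow(curve) >= 3)
  w <- if ("n_obs" %in% names(curve)) curve$n_obs else rep(1, nrow(curve))
  sse <- function(th) {
    sum(w * (curve$correct_rate -
               (th[1] * (1 - exp(-curve$n / th[2])) + th[3]))^2)
  }
  i0 <- min(curve$correct_rate[1], 0.95)
  starts <- list(c(max(curve$correct_rate) - i0, 5, i0),
                 c(0.5, 10, 0.2), c(0.8, 3, 0.1))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, sse, method = "L-BFGS-B",
                   lower = c(-1, 1e-3, 0), upper = c(2, 200, 1),
                   control = list(factr = 1e7)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("reversal fit failed", call. = FALSE)
  A <- best$par[1]; tau <- best$par[2]; I <- best$par[3]
  frac <- (0.5 - I) / A
  defined <- is.finite(frac) && frac > 0 && frac < 1
  structure(
    list(A = A, tau = tau, I = I,
         n_reverse = if (defined) -tau * log(1 - frac) else NA_real_,
         crossing_defined = defined, sse = best$value, curve = curve),
    class = "fc_reversal"
  )
}

#' Trials to reverse choice for known curve parameters
#'
#' Closed-form crossing of `f(n) = A * (1 - exp(-n / tau)) + I` through the
#' 50% correct rate.
#'
#' @param A,tau,I Exponential curve parameters.
#' @return `-tau * log(1 - (0.5 - I)/A)`, or `NA` (with a warning) when the
#'   curve does not cross 0.5 at a positive trial number.
#' @export
trials_to_reverse <- function(A, tau, I) {
  frac <- (0.5 - I) / A
  if (!is.finite(frac) || frac <= 0 || frac >= 1) {
    warning("fitted curve does not cross the 50% correct rate")
    return(NA_real_)
  }
  -tau * log(1 - frac)
}

#' @export
print.fc_reversal <- function(x, ...) {
  cat("<fc_reversal> A=", signif(x$A, 3), " tau=", signif(x$tau, 3),
      " I=", signif(x$I, 3), " n_reverse=",
      if (x$crossing_defined) signif(x$n_reverse, 4) else "undefined",
      "\n", sep = "")
  invisible(x)
}

#' History-conditioned right-choice bias for the reversing stimulus
#'
#' Quantifies the influence of the previous non-reversing stimulus on the
#' choice for the reversing stimulus. The bias following a low-frequency
#' (high-frequency) previous stimulus is the probability of a right choice
#' on those reversing-stimulus trials minus the probability of a right
#' choice averaged over all reversing-stimulus trials in low-boundary
#' (high-boundary) blocks, within the given period. Reversing-stimulus
#' previous trials do not define a history class and are excluded.
#'
#' @param trials A trial tibble.
#' @param period Period restriction: `"stable"`, `"switching"` or `"all"`.
#' @return Tibble with one row: `bias_after_low`, `bias_after_high`,
#'   `difference` (`bias_after_low - bias_after_high`), and the trial counts
#'   behind each conditional. Counts of zero leave the bias `NA`.
#' @export
right_choice_bias <- function(trials, period = c("all", "stable", "switching")) {
  period <- match.arg(period)
  lab <- trials |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(
      prev_class = dplyr::lag(dplyr::case_when(
        .data$sf_norm < 0 ~ "low", .data$sf_norm > 0 ~ "high",
        TRUE ~ "reversing"))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$is_reversing)
  if (period != "all") lab <- dplyr::filter(lab, .data$period == !!period)
  p_right <- function(d) if (nrow(d) == 0) NA_real_ else mean(d$choice == "right")
  base_low <- p_right(dplyr::filter(lab, .data$block_type == "low"))
  base_high <- p_right(dplyr::filter(lab, .data$block_type == "high"))
  # previous-low trials live in low-boundary blocks (and conversely), so the
  # conditional and its baseline are both taken in the matching block type
  after_low <- dplyr::filter(lab, .data$prev_class == "low",
                             .data$block_type == "low")
  after_high <- dplyr::filter(lab, .data$prev_class == "high",
                              .data$block_type == "high")
  bias_after_low <- p_right(after_low) - base_low
  bias_after_high <- p_right(after_high) - base_high
  tibble::tibble(
    bias_after_low = bias_after_low,
    bias_after_high = bias_after_high,
    difference = bias_after_low - bias_after_high,
    n_after_low = nrow(after_low), n_after_high = nrow(after_high),
    n_base_low = sum(lab$block_type == "low"),
    n_base_high = sum(lab$block_type == "high")
  )
}
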