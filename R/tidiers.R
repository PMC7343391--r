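#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validated model fit
#'
#' One row per parameter with the median across training fits and the
#' quartiles of the (run, fold) parameter distribution.
#'
#' @param x An `fc_fit` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `q25`, `q75`, `fixed`.
#' @export
tidy.fc_fit <- function(x, ...) {
  nm <- names(x$median_params)
  tibble::tibble(
    term = nm,
    estimate = unname(x$median_params),
    q25 = vapply(nm, function(p) stats::quantile(x$param_samples[[p]], 0.25,
                                                 names = FALSE), numeric(1)),
    q75 = vapply(nm, function(p) stats::quantile(x$param_samples[[p]], 0.75,
                                                 names = FALSE), numeric(1)),
    fixed = nm %in% names(x$variant$fixed)
  )
}

#' @rdname tidy.fc_fit
#' @return `glance()`: one row with `variant`, `cv_likelihood`,
#'   `cv_loglik`, `n_trials`, `n_free`, `n_fits`, `convergence_fail`.
#' @export
glance.fc_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant$id,
    cv_likelihood = x$cv_likelihood,
    cv_loglik = x$cv_loglik,
    n_trials = x$n_trials,
    n_free = length(x$variant$free),
    n_fits = nrow(x$param_samples),
    convergence_fail = x$diagnostics$convergence_fail
  )
}

#' Tidy a psychometric fit
#'
#' @param x An `fc_psychometric` from [fit_psychometric()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.fc_psychometric <- function(x, ...) {
  tibble::tibble(
    term = c("lapse_low", "lapse_high", "threshold", "slope"),
    estimate = c(x$lapse_low, x$lapse_high, x$threshold, x$slope)
  )
}

#' @rdname tidy.fc_psychometric
#' @export
glance.fc_psychometric <- function(x, ...) {
  tibble::tibble(nll = x$nll, degenerate = x$degenerate,
                 n_stimuli = nrow(x$counts),
                 n_trials = sum(x$counts$n_total))
}

#' Tidy a reversal-dynamics fit
#'
#' @param x An `fc_reversal` from [fit_reversal()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (`A`, `tau`, `I`,
#'   `n_reverse`).
#' @export
tidy.fc_reversal <- function(x, ...) {
  tibble::tibble(term = c("A", "tau", "I", "n_reverse"),
                 estimate = c(x$A, x$tau, x$I, x$n_reverse))
}

#' @rdname tidy.fc_reversal
#' @export
glance.fc_reversal <- function(x, ...) {
  tibble::tibble(sse = x$sse, crossing_defined = x$crossing_defined,
                 n_points = nrow(x$curve))
}

#' Tidy a parameter-recovery report
#'
#' @param x An `fc_recovery` from [recover_point()] or [recover_range()].
#' @param ... Unused.
#' @return The report tibble (one row per parameter, or per grid point and
#'   parameter for sweeps).
#' @export
tidy.fc_recovery <- function(x, ...) x$report

#' @rdname tidy.fc_recovery
#' @export
glance.fc_recovery <- function(x, ...) {
  tibble::tibble(
    variant = x$variant$id, regime = x$regime,
    all_within_tol = all(x$report$within_tol),
    rank_correlation = if (x$regime == "range_sweep") x$rank_correlation
                       else NA_real_
  )
}
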