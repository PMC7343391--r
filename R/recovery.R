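#' Parameter recovery at a single parameter point
#'
#' Simulates an agent from known parameters, refits the generating variant
#' with repeated balanced k-fold cross-validation, and reports recovered
#' medians against the originals. Agreement per free parameter is judged at
#' `|recovered - original| <= max(abs_tol, rel_tol * |original|)`.
#'
#' @param variant A [model_variant()].
#' @param params Full generating parameter vector.
#' @param sim A [sim_config()] (the reference protocol is 50 blocks per
#'   type).
#' @param cv A [cv_config()] (recovery default: 20 runs of 5-fold).
#' @param policy [init_policy()] used for fitting (and matching the
#'   simulator mode).
#' @param abs_tol,rel_tol Agreement tolerances.
#' @return An object of class `fc_recovery`: list with `variant`, `report`
#'   (tibble: `parameter`, `original`, `recovered`, `abs_error`,
#'   `rel_error`, `within_tol`), `fit` (the `fc_fit`), `sim_seed`.
#' @export
recover_point <- function(variant, params, sim = sim_config(),
                          cv = cv_config(n_runs = 20L),
                          policy = NULL,
                          abs_tol = 0.1, rel_tol = 0.15) {
  check_params(params, variant)
  if (is.null(policy)) {
    policy <- init_policy(if (sim$mode == "all_trials") "inherit"
                          else "period_reset")
  }
  trials <- simulate_agent(variant, params, sim)
  fit <- cross_validate(trials, variant, cv = cv, policy = policy,
                        config = sim$task)
  free <- variant$free
  report <- tibble::tibble(
    parameter = free,
    original = unname(params[free]),
    recovered = unname(fit$median_params[free])
  ) |>
    dplyr::mutate(
      abs_error = abs(.data$recovered - .data$original),
      rel_error = .data$abs_error / pmax(abs(.data$original), 1e-12),
      within_tol = .data$abs_error <=
        pmax(abs_tol, rel_tol * abs(.data$original))
    )
  structure(list(variant = variant, report = report, fit = fit,
                 sim_seed = sim$seed, regime = "point"),
            class = "fc_recovery")
}

#' @export
print.fc_recovery <- function(x, ...) {
  cat("<fc_recovery ", x$variant$id, "> regime=", x$regime, "\n", sep = "")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Parameter recovery along a one-parameter sweep
#'
#' Sweeps one free parameter over a grid (the other parameters fixed, e.g.
#' at the all-animal medians), runs [recover_point()] at each grid value,
#' and reports the per-point recoveries plus the rank correlation between
#' original and recovered values across the grid.
#'
#' @param variant A [model_variant()].
#' @param swept_param Name of the free parameter to sweep.
#' @param range Length-2 numeric range of original values.
#' @param n_points Number of grid points (a single point reduces to
#'   [recover_point()]).
#' @param fixed_params Full parameter vector supplying the non-swept values.
#' @param sim A [sim_config()]; each grid point uses `sim$seed + point - 1`.
#' @param cv A [cv_config()].
#' @inheritParams recover_point
#' @return An `fc_recovery` object with `regime = "range_sweep"`, `report`
#'   rows per (grid point, parameter), and `rank_correlation` (Spearman,
#'   swept parameter only).
#' @export
recover_range <- function(variant, swept_param, range, n_points,
                          fixed_params, sim = sim_config(),
                          cv = cv_config(n_runs = 20L), policy = NULL,
                          abs_tol = 0.1, rel_tol = 0.15) {
  if (!swept_param %in% variant$free) {
    stop(swept_param, " is not a free parameter of variant ", variant$id,
         call. = FALSE)
  }
  grid <- if (n_points == 1L) mean(range)
          else seq(range[1], range[2], length.out = n_points)
  reports <- purrr::imap(grid, function(v, i) {
    p <- fixed_params
    p[[swept_param]] <- v
    sim_i <- sim
    sim_i$seed <- sim$seed + i - 1L
    rec <- recover_point(variant, p, sim = sim_i, cv = cv, policy = policy,
                         abs_tol = abs_tol, rel_tol = rel_tol)
    dplyr::mutate(rec$report, point = i, swept = .data$parameter == swept_param)
  })
  report <- dplyr::bind_rows(reports)
  swept_rows <- dplyr::filter(report, .data$swept)
  rank_cor <- if (n_points >= 2) {
    stats::cor(swept_rows$original, swept_rows$recovered, method = "spearman")
  } else NA_real_
  structure(list(variant = variant, report = report,
                 rank_correlation = rank_cor, swept_param = swept_param,
                 sim_seed = sim$seed, regime = "range_sweep"),
            class = "fc_recovery")
}
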