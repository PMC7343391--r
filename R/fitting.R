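#' Cross-validation configuration
#'
#' @param n_runs Number of repeated cross-validation runs (the full protocol
#'   uses 200; recovery pipelines default to 20 for desk-scale runtime).
#' @param k Number of folds (default 5). Folds partition *blocks*, balanced
#'   by block type within one block per fold.
#' @param seed Integer seed for fold assignment and optimizer restarts.
#' @param restarts Random initializations per optimization (default 5).
#' @return A `cv_config` object.
#' @export
cv_config <- function(n_runs = 200L, k = 5L, seed = 1L, restarts = 5L) {
  stopifnot(k >= 2, n_runs >= 1, restarts >= 1)
  structure(list(n_runs = as.integer(n_runs), k = as.integer(k),
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "cv_config")
}

# box constraints used by the optimizer, per family
par_bounds <- function(family) {
  if (family == "dc") {
    list(lower = c(alpha1 = -3, alpha2 = -3, beta = -3, gamma1 = 0, gamma2 = -3),
         upper = c(alpha1 = 3, alpha2 = 3, beta = 1, gamma1 = 30, gamma2 = 3))
  } else {
    list(lower = c(alpha = 1e-3, gamma = -30),
         upper = c(alpha = 1 - 1e-3, gamma = 30))
  }
}

# documented random-initialization boxes, per family
init_boxes <- function(family) {
  if (family == "dc") {
    list(lower = c(alpha1 = -1, alpha2 = -1, beta = -0.5, gamma1 = 0.5,
                   gamma2 = -0.5),
         upper = c(alpha1 = 1, alpha2 = 1, beta = 0.9, gamma1 = 10,
                   gamma2 = 1.5))
  } else {
    list(lower = c(alpha = 0.05, gamma = 0.5),
         upper = c(alpha = 0.95, gamma = 10))
  }
}

#' Constrained maximum-likelihood fit of a choice model
#'
#' Minimizes the average negative log-likelihood of the observed choices by
#' constrained quasi-Newton search (`L-BFGS-B`) over the variant's free
#' parameters, taking the best of `restarts` random initializations drawn
#' uniformly from documented boxes. Fixed parameters of the variant are
#' never moved.
#'
#' @param trials A trial tibble, or a prepared segment list from an earlier
#'   call (internal use).
#' @param variant A [model_variant()].
#' @param policy An [init_policy()]; for `"period_reset"` the likelihood
#'   uses only the policy's periods.
#' @param restarts Number of random initializations.
#' @param config A [task_config()].
#' @param rows Optional vector of row indices of `trials` over which the
#'   average NLL is taken (used by cross-validation; the latent recursion
#'   always runs over all trials of each segment).
#' @param seed Optional seed for the initialization draws.
#' @return A list with `params` (full vector), `nll` (average, nats/trial),
#'   `convergence` (0 = converged), `restart_nlls`.
#' @export
fit_mle <- function(trials, variant, policy = init_policy(), restarts = 5L,
                    config = task_config(), rows = NULL, seed = NULL) {
  segs <- if (is.data.frame(trials)) dc_segments(trials, policy, config)
          else trials
  if (!is.null(seed)) set.seed(seed)
  bounds <- par_bounds(variant$family)
  box <- init_boxes(variant$family)
  free <- variant$free
  objective <- if (variant$family == "dc") {
    function(th) {
      full <- expand_params(stats::setNames(th, free), variant)
      segments_mean_nll(segs, full, rows)
    }
  } else {
    function(th) {
      full <- expand_params(stats::setNames(th, free), variant)
      rl_segments_mean_nll(segs, full, policy$rl_v0, rows)
    }
  }
  best <- NULL
  restart_nlls <- numeric(restarts)
  for (r in seq_len(restarts)) {
    th0 <- stats::runif(length(free), box$lower[free], box$upper[free])
    fit <- tryCatch(
      stats::optim(th0, objective, method = "L-BFGS-B",
                   lower = bounds$lower[free], upper = bounds$upper[free],
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) { restart_nlls[r] <- NA_real_; next }
    restart_nlls[r] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("optimizer failed on all ", restarts, " restarts", call. = FALSE)
  }
  params <- expand_params(stats::setNames(best$par, free), variant)
  check_params(params, variant)
  list(params = params, nll = best$value,
       convergence = best$convergence, restart_nlls = restart_nlls)
}

# Assign blocks to k folds, balanced by block type: within each type,
# blocks are shuffled and dealt round-robin, so per-fold type counts differ
# by at most one. Returns a tibble (session_id, block_index, fold).
make_folds <- function(trials, k) {
  blocks <- block_summary(trials)
  counts <- table(blocks$block_type)
  if (any(counts < k)) {
    stop("cannot balance folds: need >= ", k, " blocks per type, have ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         call. = FALSE)
  }
  blocks |>
    dplyr::group_by(.data$block_type) |>
    dplyr::mutate(fold = (sample.int(dplyr::n()) - 1L) %% k + 1L) |>
    dplyr::ungroup() |>
    dplyr::select("session_id", "block_index", "fold")
}

#' Repeated balanced k-fold cross-validation of a choice model
#'
#' For each run, blocks are partitioned into `k` folds balanced by block
#' type; for each fold, the model is fitted to the trials of the other
#' `k - 1` folds and the held-out trials are scored with the fitted
#' parameters. The criterion (or value) recursion always runs over full
#' segments in trial order, conditioning on the observed history; training
#' and held-out trials enter only their own side of the objective. The
#' cross-validated likelihood is summarized as
#' `exp(-mean held-out NLL per trial)` -- the geometric-mean per-trial
#' likelihood of held-out choices, a value in (0, 1) comparable across
#' datasets of different size.
#'
#' @param trials A trial tibble.
#' @param variant A [model_variant()].
#' @param cv A [cv_config()].
#' @param policy An [init_policy()].
#' @param config A [task_config()].
#' @return An object of class `fc_fit`: list with `variant`, `median_params`
#'   (element-wise median over all (run, fold) training fits),
#'   `param_samples` (tibble, one row per run x fold), `cv_likelihood`,
#'   `cv_loglik` (mean held-out log-likelihood per trial), `n_trials`,
#'   `fold_table`, `diagnostics`.
#' @export
cross_validate <- function(trials, variant, cv = cv_config(),
                           policy = init_policy(), config = task_config()) {
  set.seed(cv$seed)
  segs <- dc_segments(trials, policy, config)
  included_rows <- unlist(lapply(segs, `[[`, "row"), use.names = FALSE)
  trials_idx <- dplyr::mutate(trials, .row = dplyr::row_number())

  samples <- vector("list", cv$n_runs * cv$k)
  heldout_nll_sum <- 0
  heldout_n <- 0L
  fold_tables <- vector("list", cv$n_runs)
  convergence_fail <- 0L
  i <- 0L
  for (run in seq_len(cv$n_runs)) {
    folds <- make_folds(trials, cv$k)
    fold_tables[[run]] <- dplyr::mutate(folds, run = run)
    assign <- dplyr::left_join(trials_idx, folds,
                               by = c("session_id", "block_index"))
    for (f in seq_len(cv$k)) {
      train_rows <- intersect(assign$.row[assign$fold != f], included_rows)
      test_rows <- intersect(assign$.row[assign$fold == f], included_rows)
      fit <- fit_mle(segs, variant, policy, restarts = cv$restarts,
                     config = config, rows = train_rows)
      if (fit$convergence != 0) convergence_fail <- convergence_fail + 1L
      ho <- if (variant$family == "dc") {
        segments_mean_nll(segs, fit$params, test_rows)
      } else {
        rl_segments_mean_nll(segs, fit$params, policy$rl_v0, test_rows)
      }
      i <- i + 1L
      samples[[i]] <- tibble::tibble(
        run = run, fold = f, !!!as.list(fit$params),
        train_nll = fit$nll, heldout_nll = ho,
        n_test = length(test_rows)
      )
      heldout_nll_sum <- heldout_nll_sum + ho * length(test_rows)
      heldout_n <- heldout_n + length(test_rows)
    }
  }
  param_samples <- dplyr::bind_rows(samples)
  par_names <- if (variant$family == "dc") dc_par_names else rl_par_names
  median_params <- vapply(par_names,
                          function(p) stats::median(param_samples[[p]]),
                          numeric(1))
  # fixed parameters must not have moved across any training fit
  for (fx in names(variant$fixed)) {
    stopifnot(all(abs(param_samples[[fx]] - variant$fixed[[fx]]) < 1e-12))
  }
  cv_loglik <- -heldout_nll_sum / heldout_n
  structure(
    list(variant = variant, median_params = median_params,
         param_samples = param_samples,
         cv_likelihood = exp(cv_loglik), cv_loglik = cv_loglik,
         n_trials = length(included_rows),
         fold_table = dplyr::bind_rows(fold_tables),
         diagnostics = list(convergence_fail = convergence_fail,
                            policy = policy$mode, cv = cv)),
    class = "fc_fit"
  )
}

#' @export
print.fc_fit <- function(x, ...) {
  cat("<fc_fit ", x$variant$id, ">  n_trials=", x$n_trials,
      "  cv_likelihood=", signif(x$cv_likelihood, 4), "\n", sep = "")
  cat("  median params: ",
      paste(names(x$median_params), signif(x$median_params, 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare choice-model variants by cross-validated likelihood
#'
#' Cross-validates each variant on the same trials and ranks them by
#' cross-validated likelihood. Ties are broken by variant order (and
#' flagged).
#'
#' @param trials A trial tibble.
#' @param variants Character vector of variant ids, or list of
#'   [model_variant()] objects.
#' @param cv A [cv_config()].
#' @param policy An [init_policy()].
#' @param config A [task_config()].
#' @return A list with `table` (tibble: `variant`, `cv_likelihood`,
#'   `cv_loglik`, `n_free`), `best_variant` (id), `fits` (named list of
#'   `fc_fit`), `tie` (logical).
#' @export
compare_models <- function(trials, variants, cv = cv_config(),
                           policy = init_policy(), config = task_config()) {
  stopifnot(length(variants) >= 2)
  variants <- lapply(variants, function(v) {
    if (inherits(v, "model_variant")) v else model_variant(v)
  })
  ids <- vapply(variants, `[[`, character(1), "id")
  fits <- lapply(variants, function(v) {
    cross_validate(trials, v, cv = cv, policy = policy, config = config)
  })
  names(fits) <- make.unique(ids)
  tab <- tibble::tibble(
    variant = names(fits),
    cv_likelihood = vapply(fits, `[[`, numeric(1), "cv_likelihood"),
    cv_loglik = vapply(fits, `[[`, numeric(1), "cv_loglik"),
    n_free = vapply(variants, function(v) length(v$free), integer(1))
  )
  best_i <- which.max(tab$cv_likelihood)
  tie <- sum(tab$cv_likelihood == tab$cv_likelihood[best_i]) > 1
  if (tie) warning("cv-likelihood tie broken by variant order")
  list(table = tab, best_variant = tab$variant[best_i], fits = fits,
       tie = tie)
}

#' Best-model frequency across datasets
#'
#' Runs [compare_models()] on each dataset and tabulates how many datasets
#' each variant wins, the multi-animal model-comparison summary.
#'
#' @param datasets List of trial tibbles.
#' @inheritParams compare_models
#' @return Tibble with `variant` and `n_best`.
#' @export
best_model_frequency <- function(datasets, variants, cv = cv_config(),
                                 policy = init_policy(),
                                 config = task_config()) {
  wins <- vapply(datasets, function(d) {
    compare_models(d, variants, cv = cv, policy = policy,
                   config = config)$best_variant
  }, character(1))
  ids <- vapply(variants, function(v) {
    if (inherits(v, "model_variant")) v$id else v
  }, character(1))
  tibble::tibble(
    variant = ids,
    n_best = vapply(ids, function(id) sum(wins == id), integer(1))
  )
}
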