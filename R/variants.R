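#' Model variants
#'
#' The dynamic decision-criterion (DC) model has five parameters: `alpha1`
#' and `alpha2` weight the outcome of the previous reversing-stimulus trial
#' (rewarded and unrewarded choices respectively), `beta` is the drift of the
#' criterion toward zero, `gamma1` weights the current stimulus and `gamma2`
#' weights the previous non-reversing stimulus. Reduced variants fix named
#' parameters at set values:
#' `m1` (full model), `m2` (`alpha1 = 0`), `m3` (`alpha2 = 0`),
#' `m4` (`alpha1 = alpha2 = 0`), `m5` (`beta = 0`), `m6` (`gamma1 = 1`),
#' `m7` (`gamma2 = 0`). The `rl` variant is the stimulus-weighted
#' reinforcement-learning model with parameters `alpha` (learning rate) and
#' `gamma` (stimulus weight).
#'
#' @param id One of `"m1"`--`"m7"` or `"rl"`.
#' @return An object of class `model_variant`: a list with `id`, `family`
#'   (`"dc"` or `"rl"`), `fixed` (named numeric of pinned parameters) and
#'   `free` (names of free parameters).
#' @examples
#' model_variant("m4")
#' @export
model_variant <- function(id = c("m1", "m2", "m3", "m4", "m5", "m6", "m7", "rl")) {
  id <- match.arg(id)
  if (id == "rl") {
    out <- list(id = id, family = "rl", fixed = stats::setNames(numeric(0), character(0)),
                free = c("alpha", "gamma"))
  } else {
    fixed <- switch(id,
      m1 = numeric(0),
      m2 = c(alpha1 = 0),
      m3 = c(alpha2 = 0),
      m4 = c(alpha1 = 0, alpha2 = 0),
      m5 = c(beta = 0),
      m6 = c(gamma1 = 1),
      m7 = c(gamma2 = 0)
    )
    out <- list(id = id, family = "dc", fixed = fixed,
                free = setdiff(dc_par_names, names(fixed)))
  }
  structure(out, class = "model_variant")
}

dc_par_names <- c("alpha1", "alpha2", "beta", "gamma1", "gamma2")
rl_par_names <- c("alpha", "gamma")

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant ", x$id, "> family=", x$family, sep = "")
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = "=", collapse = ", "))
  }
  cat("\n  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter vectors for the choice models
#'
#' `dc_params()` builds and validates the 5-parameter vector of the dynamic
#' decision-criterion model (`gamma1 >= 0`, `beta <= 1`); `rl_params()` the
#' 2-parameter vector of the reinforcement-learning model (`0 < alpha < 1`).
#'
#' @param alpha1,alpha2 Outcome-history updates after a reversing-stimulus
#'   trial (rewarded / unrewarded choice). Positive `alpha1` is win-stay,
#'   positive `alpha2` lose-shift.
#' @param beta Criterion drift; `0 < beta < 1` decays the criterion toward 0,
#'   `beta < 0` inflates it. Constrained to `beta <= 1`.
#' @param gamma1 Weight of the current stimulus, constrained to `>= 0`.
#' @param gamma2 Weight of the previous non-reversing stimulus.
#' @return A named numeric vector.
#' @export
dc_params <- function(alpha1 = 0, alpha2 = 0, beta = 0, gamma1 = 1, gamma2 = 0) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
         gamma1 = gamma1, gamma2 = gamma2)
  check_params(p, model_variant("m1"))
  p
}

#' @param alpha Learning rate, in (0, 1).
#' @param gamma Stimulus weight of the reinforcement-learning model.
#' @rdname dc_params
#' @export
rl_params <- function(alpha = 0.5, gamma = 1) {
  p <- c(alpha = alpha, gamma = gamma)
  check_params(p, model_variant("rl"))
  p
}

# validate a full parameter vector against family constraints and the
# variant's fixed-value mask
check_params <- function(params, variant) {
  nm <- if (variant$family == "dc") dc_par_names else rl_par_names
  if (!all(nm %in% names(params))) {
    stop("params must contain: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  params <- params[nm]
  if (any(!is.finite(params))) stop("params must be finite", call. = FALSE)
  if (variant$family == "dc") {
    if (params[["gamma1"]] < 0) stop("gamma1 must be >= 0", call. = FALSE)
    if (params[["beta"]] > 1) stop("beta must be <= 1", call. = FALSE)
  } else {
    if (params[["alpha"]] <= 0 || params[["alpha"]] >= 1) {
      stop("alpha must be in (0, 1)", call. = FALSE)
    }
  }
  for (f in names(variant$fixed)) {
    if (abs(params[[f]] - variant$fixed[[f]]) > 1e-12) {
      stop("variant ", variant$id, " fixes ", f, " = ", variant$fixed[[f]],
           call. = FALSE)
    }
  }
  invisible(params)
}

# expand a free-parameter vector to the full parameter vector of the variant
expand_params <- function(free, variant) {
  nm <- if (variant$family == "dc") dc_par_names else rl_par_names
  full <- stats::setNames(numeric(length(nm)), nm)
  full[names(variant$fixed)] <- variant$fixed
  full[variant$free] <- free[variant$free]
  full
}

#' Serialize and restore model parameters
#'
#' Writes a parameter vector with its variant id (and fixed-parameter mask)
#' to JSON, and reads it back.
#'
#' @param params Named parameter vector.
#' @param variant A [model_variant()].
#' @param path File path.
#' @return `read_params()` returns a list with `params` and `variant`.
#' @export
write_params <- function(params, variant, path) {
  check_params(params, variant)
  jsonlite::write_json(
    list(variant = variant$id, fixed = as.list(variant$fixed),
         params = as.list(params)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variant <- model_variant(x$variant)
  params <- unlist(x$params)
  check_params(params, variant)
  list(params = params, variant = variant)
}
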