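#' Probability of a right choice under the dynamic-DC model
#'
#' The decision variable is `z = gamma1 * s - dc`, the weighted current
#' stimulus minus the decision criterion, and the probability of choosing
#' right is the logistic `1 / (1 + exp(-z))`.
#'
#' @param gamma1 Current-stimulus weight (>= 0).
#' @param s Normalized stimulus in \[-1, 1\].
#' @param dc Decision criterion.
#' @return Probability of a right choice; vectorized over `s` and `dc`.
#' @export
choice_prob_right <- function(gamma1, s, dc) {
  stopifnot(all(gamma1 >= 0))
  stats::plogis(gamma1 * s - dc)
}

#' One trial-history update of the decision criterion
#'
#' After a reversing-stimulus trial the criterion is updated by the outcome:
#' `dc <- (1 - beta) * dc + alpha1` for a rewarded left choice,
#' `- alpha1` for a rewarded right choice, `- alpha2` for an unrewarded left
#' choice and `+ alpha2` for an unrewarded right choice. After a
#' non-reversing trial the criterion follows the sensory history,
#' `dc <- (1 - beta) * dc + gamma2 * s_prev`. Because the reversing stimulus
#' has `s_prev = 0`, the two branches agree on reversing trials whenever the
#' outcome terms are zero.
#'
#' @param params Full DC parameter vector (see [dc_params()]).
#' @param dc_prev Criterion after the previous trial.
#' @param prev One-row trial record (needs `is_reversing`, `choice`,
#'   `rewarded`, `sf_norm`), or a list with those fields.
#' @return Updated criterion (scalar).
#' @export
update_dc <- function(params, dc_prev, prev) {
  base <- (1 - params[["beta"]]) * dc_prev
  if (isTRUE(prev$is_reversing)) {
    sgn <- if (prev$choice == "left") 1 else -1
    if (isTRUE(prev$rewarded)) base + sgn * params[["alpha1"]]
    else base - sgn * params[["alpha2"]]
  } else {
    base + params[["gamma2"]] * prev$sf_norm
  }
}

#' Initialization policy for the criterion recursion
#'
#' Two modes are supported. `"inherit"`: the criterion starts at 0 on the
#' first trial of a session and is carried across block boundaries, so one
#' recursion runs over all trials of the session (the policy used when
#' fitting or simulating all trials). `"period_reset"`: only stable and
#' switching period trials enter the likelihood, and the criterion is reset
#' at the first trial of every period segment to the value implied by the
#' task's switch rule -- at a switch the reversing-stimulus correct rate is
#' `switch_criterion` (say 0.70) just before and its complement just after,
#' and with `s = 0` the correct rate ties directly to the criterion through
#' the logistic, giving `dc = -qlogis(criterion)` in low-boundary stable
#' segments, `+qlogis(criterion)` in high-boundary stable segments, and the
#' sign-flipped values in switching segments.
#'
#' @param mode `"inherit"` or `"period_reset"`.
#' @param periods Which periods enter a `"period_reset"` likelihood.
#' @param rl_v0 Initial left/right choice values of the RL model at each
#'   segment start.
#' @return An `init_policy` object.
#' @export
init_policy <- function(mode = c("inherit", "period_reset"),
                        periods = c("stable", "switching"),
                        rl_v0 = c(1, 1)) {
  mode <- match.arg(mode)
  periods <- match.arg(periods, c("stable", "switching"), several.ok = TRUE)
  stopifnot(length(rl_v0) == 2, all(is.finite(rl_v0)))
  structure(list(mode = mode, periods = periods, rl_v0 = rl_v0),
            class = "init_policy")
}

#' Criterion value implied by a reversing-stimulus correct rate
#'
#' Used by the `"period_reset"` policy: in a `block_type` block during
#' `period`, the criterion that makes the reversing-stimulus correct rate
#' equal to `criterion` (stable) or `1 - criterion` (switching).
#'
#' @param block_type `"low"` or `"high"`.
#' @param period `"stable"` or `"switching"`.
#' @param criterion The task's switch criterion (e.g. 0.70).
#' @return Criterion value (scalar); e.g. `-log(7/3)` for a low-boundary
#'   stable segment at criterion 0.70.
#' @export
period_dc_init <- function(block_type, period, criterion = 0.70) {
  b <- stats::qlogis(criterion)
  n <- max(length(block_type), length(period))
  sgn <- ifelse(rep_len(check_block_type(block_type), n) == "low", -1, 1)
  ifelse(rep_len(period, n) == "stable", sgn * b, -sgn * b)
}

# Split a trial table into recursion segments according to the policy.
# Returns a list of segments; each segment carries the design vectors the
# likelihood needs:
#   s      current normalized stimulus
#   y      1 for right choice, 0 for left
#   w1,w2  outcome-update design (per trial t, from trial t-1): w1 = +-1 on
#          trials after a rewarded reversing trial (sign + for left choice),
#          w2 = -+1 after an unrewarded reversing trial (sign - for left)
#   sp     previous-trial stimulus (0 after a reversing trial)
#   dc0    criterion before the first trial of the segment
#   row    row indices into the original table
#   s01, prev_* extra columns used by the RL recursion
dc_segments <- function(trials, policy = init_policy(), config = task_config()) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  trials <- dplyr::mutate(trials, .row = dplyr::row_number())
  if (policy$mode == "inherit") {
    groups <- split(trials, factor(trials$session_id,
                                   levels = unique(trials$session_id)))
    segs <- lapply(groups, function(g) make_segment(g, dc0 = 0))
  } else {
    keep <- trials[trials$period %in% policy$periods, ]
    if (nrow(keep) == 0) stop("no trials in the requested periods", call. = FALSE)
    keep <- keep |>
      dplyr::group_by(.data$session_id, .data$block_index, .data$period) |>
      dplyr::mutate(.seg = dplyr::cur_group_id()) |>
      dplyr::ungroup()
    segs <- lapply(split(keep, keep$.seg), function(g) {
      make_segment(g, dc0 = period_dc_init(g$block_type[1], g$period[1],
                                           config$switch_criterion))
    })
  }
  unname(segs)
}

make_segment <- function(g, dc0) {
  n <- nrow(g)
  is_rev <- g$is_reversing
  left <- g$choice == "left"
  rew <- g$rewarded
  # design at trial t comes from trial t-1; first trial has no history term
  lag1 <- function(x, fill = FALSE) c(fill, x[-n])
  prev_rev <- lag1(is_rev)
  prev_left <- lag1(left)
  prev_rew <- lag1(rew)
  sgn <- ifelse(prev_left, 1, -1)
  list(
    n = n,
    s = g$sf_norm,
    s01 = g$sf_norm01,
    y = as.integer(!left),
    w1 = ifelse(prev_rev & prev_rew, sgn, 0),
    w2 = ifelse(prev_rev & !prev_rew, -sgn, 0),
    sp = c(0, g$sf_norm[-n]) * as.numeric(!prev_rev),
    prev_left = prev_left,
    prev_rew = prev_rew,
    rewarded_obs = rew,
    has_prev = c(FALSE, rep(TRUE, n - 1L)),
    dc0 = dc0,
    row = g$.row
  )
}

# Criterion trajectory of one segment: linear recursion
# dc_t = (1 - beta) dc_{t-1} + u_t with u_t the history input, run at C
# speed through stats::filter.
segment_dc <- function(seg, params) {
  u <- params[["alpha1"]] * seg$w1 + params[["alpha2"]] * seg$w2 +
    params[["gamma2"]] * seg$sp
  if (seg$n == 1L) return(seg$dc0)
  rest <- stats::filter(u[-1L], 1 - params[["beta"]],
                        method = "recursive", init = seg$dc0)
  c(seg$dc0, as.numeric(rest))
}

# per-trial negative log-likelihood over prepared segments; probabilities
# clipped to [1e-12, 1 - 1e-12] to keep the sum finite
PROB_CLIP <- 1e-12

segments_nll_vec <- function(segs, params) {
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    dc <- segment_dc(seg, params)
    p <- stats::plogis(params[["gamma1"]] * seg$s - dc)
    p <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
    out[[i]] <- -log(ifelse(seg$y == 1L, p, 1 - p))
  }
  out
}

#' Average negative log-likelihood of the dynamic-DC model
#'
#' Runs the criterion recursion over the trial table under the given
#' initialization policy and returns the average negative log-likelihood of
#' the observed choices (nats/trial) together with the latent trajectory.
#'
#' @param trials A trial tibble (see [fc_trials()]).
#' @param params Full DC parameter vector (see [dc_params()]).
#' @param variant A [model_variant()] whose fixed-parameter mask `params`
#'   must respect.
#' @param policy An [init_policy()].
#' @param config A [task_config()] (supplies the switch criterion used by
#'   period resets).
#' @return A list with `nll` (average, nats/trial), `n_trials`, and
#'   `trajectory`: a tibble with `row` (row in `trials`), `dc`, `z`,
#'   `p_right`, `nll` per included trial.
#' @export
dc_nll <- function(trials, params, variant = model_variant("m1"),
                   policy = init_policy(), config = task_config()) {
  check_params(params, variant)
  segs <- dc_segments(trials, policy, config)
  traj <- purrr::map_dfr(segs, function(seg) {
    dc <- segment_dc(seg, params)
    z <- params[["gamma1"]] * seg$s - dc
    p <- pmin(pmax(stats::plogis(z), PROB_CLIP), 1 - PROB_CLIP)
    tibble::tibble(
      row = seg$row, dc = dc, z = z, p_right = p,
      nll = -log(ifelse(seg$y == 1L, p, 1 - p))
    )
  })
  list(nll = mean(traj$nll), n_trials = nrow(traj), trajectory = traj)
}

# fast path used by the optimizer: mean NLL over (optionally) a subset of
# trials, identified by row index in the original table
segments_mean_nll <- function(segs, params, rows = NULL) {
  nll <- segments_nll_vec(segs, params)
  if (is.null(rows)) return(mean(unlist(nll, use.names = FALSE)))
  tot <- 0
  cnt <- 0L
  for (i in seq_along(segs)) {
    m <- segs[[i]]$row %in% rows
    tot <- tot + sum(nll[[i]][m])
    cnt <- cnt + sum(m)
  }
  if (cnt == 0L) stop("no trials selected for likelihood", call. = FALSE)
  tot / cnt
}
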