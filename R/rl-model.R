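#' Stimulus-weighted reinforcement-learning choice model
#'
#' An alternative to the dynamic-criterion model with no internal boundary:
#' left and right choices carry learned values `v_left`, `v_right`; on each
#' trial the expected values are the learned values weighted by the current
#' stimulus, `q_left = gamma * (1 - s01) * v_left` and
#' `q_right = gamma * s01 * v_right` (with `s01` the stimulus normalized to
#' \[0, 1\]), and the choice probability is the softmax of the two. After
#' the outcome, only the chosen side's value is updated by the reward
#' prediction error: `v <- v + alpha * (r - q_chosen)` with reward `r` coded
#' 1/0.
#'
#' `rl_step()` computes the expected values and choice probability for a
#' stimulus; `rl_update()` applies the value update for an observed outcome.
#'
#' @param params RL parameter vector (see [rl_params()]).
#' @param state List with `v_left`, `v_right` (and after [rl_step()] also
#'   `q_left`, `q_right`, `p_right`).
#' @param s01 Stimulus normalized in \[0, 1\].
#' @return An updated state list.
#' @export
rl_step <- function(params, state, s01) {
  stopifnot(s01 >= 0, s01 <= 1)
  g <- params[["gamma"]]
  ql <- g * (1 - s01) * state$v_left
  qr <- g * s01 * state$v_right
  m <- max(ql, qr)
  pr <- exp(qr - m) / (exp(ql - m) + exp(qr - m))
  list(v_left = state$v_left, v_right = state$v_right,
       q_left = ql, q_right = qr, p_right = pr)
}

#' @param choice `"left"` or `"right"`, the choice taken.
#' @param rewarded Logical outcome of that choice.
#' @rdname rl_step
#' @export
rl_update <- function(params, state, choice, rewarded) {
  a <- params[["alpha"]]
  r <- as.numeric(rewarded)
  if (choice == "left") {
    state$v_left <- state$v_left + a * (r - state$q_left)
  } else {
    state$v_right <- state$v_right + a * (r - state$q_right)
  }
  state
}

#' Average negative log-likelihood of the RL model
#'
#' Runs the value recursion over the trial table (values reset to
#' `policy$rl_v0` at the start of every segment defined by the policy) and
#' returns the average negative log-likelihood of the observed choices.
#'
#' @inheritParams dc_nll
#' @param params RL parameter vector (see [rl_params()]).
#' @return A list with `nll`, `n_trials` and `trajectory` (tibble with
#'   `row`, `v_left`, `v_right`, `q_left`, `q_right`, `p_right`, `nll`).
#' @export
rl_nll <- function(trials, params, policy = init_policy(),
                   config = task_config()) {
  check_params(params, model_variant("rl"))
  segs <- dc_segments(trials, policy, config)
  traj <- purrr::map_dfr(segs, function(seg) rl_segment(seg, params, policy$rl_v0))
  list(nll = mean(traj$nll), n_trials = nrow(traj), trajectory = traj)
}

# sequential value recursion over one segment; returns the per-trial trace
rl_segment <- function(seg, params, v0) {
  n <- seg$n
  a <- params[["alpha"]]
  g <- params[["gamma"]]
  vl <- numeric(n); vr <- numeric(n)
  ql <- numeric(n); qr <- numeric(n)
  pr <- numeric(n)
  cvl <- v0[1]; cvr <- v0[2]
  left <- seg$y == 0L
  s01 <- seg$s01
  for (t in seq_len(n)) {
    cql <- g * (1 - s01[t]) * cvl
    cqr <- g * s01[t] * cvr
    m <- max(cql, cqr)
    p <- exp(cqr - m) / (exp(cql - m) + exp(cqr - m))
    vl[t] <- cvl; vr[t] <- cvr; ql[t] <- cql; qr[t] <- cqr; pr[t] <- p
    # value update from this trial's observed choice and outcome
    r <- as.numeric(seg$rewarded_obs[t])
    if (left[t]) cvl <- cvl + a * (r - cql) else cvr <- cvr + a * (r - cqr)
  }
  pr <- pmin(pmax(pr, PROB_CLIP), 1 - PROB_CLIP)
  tibble::tibble(
    row = seg$row, v_left = vl, v_right = vr,
    q_left = ql, q_right = qr, p_right = pr,
    nll = -log(ifelse(left, 1 - pr, pr))
  )
}

# mean NLL over a row subset, RL family
rl_segments_mean_nll <- function(segs, params, v0, rows = NULL) {
  tot <- 0; cnt <- 0L
  for (seg in segs) {
    tr <- rl_segment(seg, params, v0)
    m <- if (is.null(rows)) rep(TRUE, seg$n) else seg$row %in% rows
    tot <- tot + sum(tr$nll[m])
    cnt <- cnt + sum(m)
  }
  if (cnt == 0L) stop("no trials selected for likelihood", call. = FALSE)
  tot / cnt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
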