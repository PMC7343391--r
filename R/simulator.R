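#' Simulation configuration
#'
#' @param n_blocks_per_type Number of blocks of each type in the simulated
#'   session (50 of each, the reference simulation protocol for this
#'   task).
#' @param mode `"all_trials"`: the criterion is carried across blocks
#'   (inherit policy). `"period_reset"`: the criterion is re-initialized from
#'   the switch rule -- to the switching-period value at each block start and
#'   to the stable-period value once the block reaches
#'   `min_block_trials - period_length` trials (the earliest trial at which
#'   the closing stable period can begin).
#' @param seed Integer seed; identical configs and parameters give
#'   bit-identical datasets.
#' @param task A [task_config()].
#' @param inactivation_scale Optional named numeric of multiplicative
#'   parameter scalings applied before simulating (see
#'   [apply_inactivation()]).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_blocks_per_type = 50L,
                       mode = c("all_trials", "period_reset"),
                       seed = 1L,
                       task = task_config(),
                       inactivation_scale = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_blocks_per_type >= 1)
  if (!is.null(inactivation_scale)) {
    stopifnot(is.numeric(inactivation_scale),
              !is.null(names(inactivation_scale)),
              all(is.finite(inactivation_scale)))
  }
  structure(list(n_blocks_per_type = as.integer(n_blocks_per_type),
                 mode = mode, seed = as.integer(seed), task = task,
                 inactivation_scale = inactivation_scale),
            class = "sim_config")
}

#' Draw a stimulus for a block type
#'
#' The two block-frequent stimuli (SF1 and SF4 in low-boundary blocks, SF4
#' and SF7 in high-boundary blocks) jointly carry `frequent_prob` of the
#' mass, split equally; the remaining five stimuli split the rest equally.
#'
#' @param block_type `"low"` or `"high"`.
#' @param config A [task_config()].
#' @param n Number of draws.
#' @return Numeric vector of spatial frequencies.
#' @export
sample_stimulus <- function(block_type, config = task_config(), n = 1L) {
  probs <- stimulus_probs(check_block_type(block_type)[1], config)
  sample(config$sf_values, n, replace = TRUE, prob = probs)
}

stimulus_probs <- function(block_type, config) {
  k <- length(config$sf_values)
  frequent <- if (block_type == "low") c(1L, config$reversing_index)
              else c(config$reversing_index, k)
  probs <- rep((1 - config$frequent_prob) / (k - 2L), k)
  probs[frequent] <- config$frequent_prob / 2
  probs
}

#' Scale model parameters to emulate an inactivation condition
#'
#' Multiplies named free parameters by the given factors and re-checks the
#' variant's constraints, e.g. scaling down the sensory-history weight
#' `gamma2` to emulate a reduced influence of the previous stimulus.
#'
#' @param params Full parameter vector.
#' @param variant A [model_variant()].
#' @param scale_map Named numeric of multipliers; names must be free
#'   parameters of the variant. An empty map is the identity.
#' @return The scaled parameter vector.
#' @export
apply_inactivation <- function(params, variant, scale_map = NULL) {
  if (is.null(scale_map) || length(scale_map) == 0) return(params)
  bad <- setdiff(names(scale_map), variant$free)
  if (length(bad) > 0) {
    stop("not free parameter(s) of variant ", variant$id, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params[names(scale_map)] <- params[names(scale_map)] * scale_map
  check_params(params, variant)
  params
}

#' Simulate an agent through the boundary-switching task
#'
#' Runs a choice model as a generative agent: stimuli are drawn from the
#' block's statistics, the choice on each trial is Bernoulli in the model's
#' right-choice probability, reward follows the block's category rule, and
#' the boundary switches once the block has at least `min_block_trials`
#' trials and the fraction correct over the last `switch_window`
#' reversing-stimulus trials reaches `switch_criterion` (evaluated only
#' once the block has seen `switch_window` reversing-stimulus trials). The
#' session contains exactly `n_blocks_per_type` blocks of each type,
#' alternating, the first type drawn at random. A block that exceeds
#' `max_block_trials` without meeting the criterion is force-switched and
#' counted in the `forced_switches` attribute.
#'
#' @param variant A [model_variant()].
#' @param params Full parameter vector for the variant (DC or RL family).
#' @param sim A [sim_config()].
#' @param session_id Session identifier for the output table.
#' @return An `fc_trials` tibble with attributes `latent` (per-trial latent
#'   trace: `dc`/`p_right` for the DC family, values for RL), `seed`,
#'   `forced_switches` and `provenance = "simulated"`.
#' @export
simulate_agent <- function(variant, params, sim = sim_config(),
                           session_id = "sim") {
  params <- apply_inactivation(params, variant, sim$inactivation_scale)
  check_params(params, variant)
  cfg <- sim$task
  set.seed(sim$seed)

  n_blocks <- 2L * sim$n_blocks_per_type
  first_low <- stats::runif(1) < 0.5
  types <- rep(if (first_low) c("low", "high") else c("high", "low"),
               sim$n_blocks_per_type)

  cap <- n_blocks * cfg$max_block_trials
  sf <- numeric(cap); block_i <- integer(cap); btype <- character(cap)
  choice <- character(cap); rewarded <- logical(cap)
  dc_tr <- numeric(cap); p_tr <- numeric(cap)
  vl_tr <- numeric(cap); vr_tr <- numeric(cap)

  is_dc <- variant$family == "dc"
  dc <- 0                                      # session-start criterion
  state <- list(v_left = 1, v_right = 1)
  crit_b <- stats::qlogis(cfg$switch_criterion)
  stable_reset_at <- cfg$min_block_trials - cfg$period_length
  forced <- 0L
  t <- 0L
  prev <- NULL

  for (blk in seq_len(n_blocks)) {
    bt <- types[blk]
    probs <- stimulus_probs(bt, cfg)
    rev_correct <- logical(0)               # outcome history, reversing trials
    len <- 0L
    repeat {
      len <- len + 1L; t <- t + 1L
      # a period reset overrides the trial-history update on the trial it
      # lands on; otherwise the criterion/values carry the previous trial's
      # update (inherited across blocks in all_trials mode)
      reset_now <- sim$mode == "period_reset" && is_dc &&
        (len == 1L || len == stable_reset_at + 1L)
      if (reset_now) {
        dc <- period_dc_init(bt, if (len == 1L) "switching" else "stable",
                             cfg$switch_criterion)
      } else if (!is.null(prev)) {
        if (is_dc) dc <- update_dc(params, dc, prev)
        else state <- rl_update(params, state, prev$choice, prev$rewarded)
      }
      f <- sample.int(7L, 1L, prob = probs)
      s <- normalize_sf(cfg$sf_values[f], cfg)
      if (is_dc) {
        p <- choice_prob_right(params[["gamma1"]], s, dc)
      } else {
        state <- rl_step(params, state, normalize_sf01(cfg$sf_values[f], cfg))
        p <- state$p_right
      }
      ch <- if (stats::runif(1) < p) "right" else "left"
      rw <- ch == correct_side(s, bt)
      sf[t] <- cfg$sf_values[f]; block_i[t] <- blk - 1L; btype[t] <- bt
      choice[t] <- ch; rewarded[t] <- rw
      if (is_dc) { dc_tr[t] <- dc; p_tr[t] <- p }
      else { vl_tr[t] <- state$v_left; vr_tr[t] <- state$v_right; p_tr[t] <- p }
      if (s == 0) rev_correct <- c(rev_correct, rw)
      prev <- list(is_reversing = s == 0, choice = ch, rewarded = rw,
                   sf_norm = s)
      nrev <- length(rev_correct)
      met <- len >= cfg$min_block_trials && nrev >= cfg$switch_window &&
        mean(rev_correct[(nrev - cfg$switch_window + 1L):nrev]) >=
          cfg$switch_criterion
      if (met) break
      if (len >= cfg$max_block_trials) { forced <- forced + 1L; break }
    }
  }
  if (forced > 0L) {
    warning(forced, " block(s) force-switched at max_block_trials")
  }
  idx <- seq_len(t)
  trials <- fc_trials(session_id, block_i[idx], btype[idx], sf[idx],
                      choice[idx], rewarded[idx], config = cfg)
  latent <- if (is_dc) {
    tibble::tibble(dc = dc_tr[idx], p_right = p_tr[idx])
  } else {
    tibble::tibble(v_left = vl_tr[idx], v_right = vr_tr[idx],
                   p_right = p_tr[idx])
  }
  attr(trials, "latent") <- latent
  attr(trials, "seed") <- sim$seed
  attr(trials, "forced_switches") <- forced
  attr(trials, "provenance") <- "simulated"
  trials
}
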