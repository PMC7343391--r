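# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately re-derive quantities with plain arithmetic loops so
# they share no code path with the package implementation.

# an exactly log-spaced 7-frequency set (keeps normalization values rational)
exact_sfs <- function() 0.03 * (10^(1 / 6))^(0:6) # 0.03 ... 0.3, ratio 10^(1/6)

exact_cfg <- function(...) task_config(sf_values = exact_sfs(), ...)

# hand-build a trial table: blocks alternate, choices given explicitly
tiny_trials <- function(sf, choice, block_type = "low", session = "s1",
                        config = task_config()) {
  n <- length(sf)
  fc_trials(session_id = session, block_index = 0L,
            block_type = block_type, sf = sf, choice = choice,
            config = config)
}

# sequential brute-force evaluation of the dynamic-DC likelihood: a plain
# loop over trials implementing the criterion update rules directly
oracle_dc_nll <- function(trials, alpha1, alpha2, beta, gamma1, gamma2,
                          dc0 = 0) {
  nll <- 0
  dc <- dc0
  for (t in seq_len(nrow(trials))) {
    if (t > 1) {
      pr <- trials[t - 1, ]
      if (pr$sf_norm == 0) {
        if (pr$rewarded && pr$choice == "left") dc <- (1 - beta) * dc + alpha1
        else if (pr$rewarded && pr$choice == "right") dc <- (1 - beta) * dc - alpha1
        else if (!pr$rewarded && pr$choice == "left") dc <- (1 - beta) * dc - alpha2
        else dc <- (1 - beta) * dc + alpha2
      } else {
        dc <- (1 - beta) * dc + gamma2 * pr$sf_norm
      }
    }
    z <- gamma1 * trials$sf_norm[t] - dc
    p <- 1 / (1 + exp(-z))
    obs <- if (trials$choice[t] == "right") p else 1 - p
    obs <- min(max(obs, 1e-12), 1 - 1e-12)  # the documented likelihood clip
    nll <- nll - log(obs)
  }
  nll / nrow(trials)
}

# sequential brute-force RL likelihood
oracle_rl_nll <- function(trials, alpha, gamma, v0 = c(1, 1)) {
  vl <- v0[1]; vr <- v0[2]
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    s <- trials$sf_norm01[t]
    ql <- gamma * (1 - s) * vl
    qr <- gamma * s * vr
    p <- exp(qr) / (exp(ql) + exp(qr))
    obs <- if (trials$choice[t] == "right") p else 1 - p
    obs <- min(max(obs, 1e-12), 1 - 1e-12)
    nll <- nll - log(obs)
    r <- as.numeric(trials$rewarded[t])
    if (trials$choice[t] == "left") vl <- vl + alpha * (r - ql)
    else vr <- vr + alpha * (r - qr)
  }
  nll / nrow(trials)
}

# exhaustive all-pairs auROC: P(b > a) + 0.5 P(b == a)
oracle_roc_preference <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (y > x) + 0.5 * (y == x)
  }
  2 * (wins / (length(a) * length(b)) - 0.5)
}

# printed all-animal median parameter vectors used throughout
medians_m1 <- function() dc_params(alpha1 = -0.13, alpha2 = 0.13,
                                   beta = 0.22, gamma1 = 3.64, gamma2 = 0.42)
medians_m4 <- function() dc_params(beta = 0.21, gamma1 = 3.61, gamma2 = 0.36)

# small simulated dataset shared by several test files
sim_small <- function(variant = "m4", params = medians_m4(),
                      n_blocks = 8L, seed = 101L, mode = "all_trials") {
  simulate_agent(model_variant(variant), params,
                 sim_config(n_blocks_per_type = n_blocks, seed = seed,
                            mode = mode))
}
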