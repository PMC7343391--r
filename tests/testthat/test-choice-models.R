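test_that("the logistic choice rule has the stated closed-form values", {
  expect_equal(choice_prob_right(1, 0, 0), 0.5)
  expect_equal(choice_prob_right(3.64, 1, 0), 1 / (1 + exp(-3.64)))
  expect_equal(choice_prob_right(3.64, -1, 0), 1 - 1 / (1 + exp(-3.64)))
  # antisymmetry: p(g, s, dc) + p(g, -s, -dc) = 1, over random inputs
  set.seed(1)
  for (i in 1:50) {
    g <- runif(1, 0, 10); s <- runif(1, -1, 1); dc <- rnorm(1, 0, 2)
    expect_equal(choice_prob_right(g, s, dc) +
                   choice_prob_right(g, -s, -dc), 1)
  }
  # monotone in s, antitone in dc
  expect_true(all(diff(choice_prob_right(2, seq(-1, 1, 0.1), 0.3)) > 0))
  expect_true(all(diff(choice_prob_right(2, 0.2, seq(-2, 2, 0.1))) < 0))
  expect_error(choice_prob_right(-1, 0, 0))
})

test_that("criterion updates follow the outcome- and sensory-history rules", {
  p <- dc_params(alpha1 = -0.13, alpha2 = 0.13, beta = 0.22, gamma1 = 3.64,
                 gamma2 = 0.42)
  rewarded_left <- list(is_reversing = TRUE, choice = "left",
                        rewarded = TRUE, sf_norm = 0)
  expect_equal(update_dc(p, 1.0, rewarded_left), 0.78 * 1.0 - 0.13)
  rewarded_right <- list(is_reversing = TRUE, choice = "right",
                         rewarded = TRUE, sf_norm = 0)
  expect_equal(update_dc(p, 1.0, rewarded_right), 0.78 * 1.0 + 0.13)
  unrew_left <- list(is_reversing = TRUE, choice = "left",
                     rewarded = FALSE, sf_norm = 0)
  expect_equal(update_dc(p, 1.0, unrew_left), 0.78 * 1.0 - 0.13)
  unrew_right <- list(is_reversing = TRUE, choice = "right",
                      rewarded = FALSE, sf_norm = 0)
  expect_equal(update_dc(p, 1.0, unrew_right), 0.78 * 1.0 + 0.13)
  # sensory history after a non-reversing trial
  p2 <- dc_params(beta = 0, gamma2 = 0.42)
  prev_low <- list(is_reversing = FALSE, choice = "left", rewarded = TRUE,
                   sf_norm = -1)
  expect_equal(update_dc(p2, 0, prev_low), -0.42)
  # variant m4 forces the outcome updates to zero: pure drift on reversing
  p4 <- medians_m4()
  expect_equal(update_dc(p4, 0.6, rewarded_left), (1 - 0.21) * 0.6)
  expect_equal(update_dc(p4, 0.6, unrew_right), (1 - 0.21) * 0.6)
})

test_that("period-reset initialization matches the switch-rule correct rates", {
  b <- log(7 / 3)
  expect_equal(period_dc_init("low", "stable", 0.70), -b)
  expect_equal(period_dc_init("high", "stable", 0.70), b)
  expect_equal(period_dc_init("low", "switching", 0.70), b)
  expect_equal(period_dc_init("high", "switching", 0.70), -b)
  expect_equal(period_dc_init("low", "stable", 0.80), -log(4))
  # with s = 0 the implied reversing-stimulus correct rate is recovered
  expect_equal(choice_prob_right(3.64, 0, period_dc_init("low", "stable")),
               0.70)
  expect_equal(choice_prob_right(3.64, 0, period_dc_init("low", "switching")),
               0.30)
})

test_that("dynamic-DC likelihood equals sequential brute-force evaluation", {
  cfg <- exact_cfg()
  sfs <- cfg$sf_values
  # 5 hand-constructed trials mixing reversing and non-reversing history
  tr <- tiny_trials(sf = sfs[c(4, 1, 4, 7, 4)],
                    choice = c("right", "left", "left", "right", "right"),
                    config = cfg)
  pars <- list(alpha1 = -0.3, alpha2 = 0.25, beta = 0.15, gamma1 = 2.5,
               gamma2 = 0.6)
  got <- dc_nll(tr, do.call(dc_params, pars), model_variant("m1"),
                config = cfg)
  expect_equal(got$nll, do.call(oracle_dc_nll, c(list(tr), pars)),
               tolerance = 1e-12)
  # property: agreement on random datasets and parameters
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    trr <- tiny_trials(sf = sample(sfs, n, replace = TRUE),
                       choice = sample(c("left", "right"), n, replace = TRUE),
                       config = cfg)
    pr <- list(alpha1 = runif(1, -1, 1), alpha2 = runif(1, -1, 1),
               beta = runif(1, -0.5, 0.9), gamma1 = runif(1, 0, 8),
               gamma2 = runif(1, -1, 1.5))
    # tolerance allows for floating-point loss in 1 - p near saturation
    expect_equal(dc_nll(trr, do.call(dc_params, pr), config = cfg)$nll,
                 do.call(oracle_dc_nll, c(list(trr), pr)),
                 tolerance = 1e-6)
  }
})

test_that("likelihood limits: chance baseline and deterministic saturation", {
  tr <- sim_small(n_blocks = 3L, seed = 77L)
  # gamma1 = 0 and a criterion that never moves: p = 0.5 on every trial
  p0 <- dc_params(gamma1 = 0)
  expect_equal(dc_nll(tr, p0)$nll, log(2), tolerance = 1e-12)
  # RL with gamma = 0: symmetric softmax, same chance baseline
  expect_equal(rl_nll(tr, rl_params(alpha = 0.3, gamma = 0))$nll, log(2))
  # choices generated near-deterministically from a steep model
  p_steep <- dc_params(gamma1 = 50)
  sim <- simulate_agent(model_variant("m7"), p_steep,
                        sim_config(n_blocks_per_type = 2L, seed = 3L))
  got <- dc_nll(sim, p_steep)
  expect_lt(mean(got$trajectory$nll[!sim$is_reversing]), 0.01)
})

test_that("criterion drift is geometric in (1 - beta)", {
  cfg <- exact_cfg()
  # stable segment of reversing trials, outcome updates forced to zero:
  # dc_t = (1 - beta)^t dc_0 exactly
  tr <- fc_trials("s1", rep(0:1, each = 100L), rep(c("low", "high"), each = 100L),
                  rep(cfg$sf_values[4], 200L), rep("left", 200L), config = cfg)
  pol <- init_policy("period_reset", periods = "stable")
  for (beta in c(0.3, -0.2)) {
    p <- dc_params(beta = beta, gamma1 = 1)
    traj <- dc_nll(tr, p, model_variant("m4"), policy = pol,
                   config = cfg)$trajectory
    dc <- traj$dc[seq_len(15)]
    expect_equal(dc, period_dc_init("low", "stable") * (1 - beta)^(0:14))
    if (beta > 0) expect_true(all(diff(abs(dc)) < 0))  # decays toward 0
    else expect_true(all(diff(abs(dc)) > 0))           # inflates
  }
})

test_that("likelihood decomposes over segments under period resets", {
  tr <- sim_small(n_blocks = 6L, seed = 55L)
  p <- medians_m4()
  pol <- init_policy("period_reset")
  whole <- dc_nll(tr, p, model_variant("m4"), policy = pol)
  # blockwise: split the table by block, keep the same per-segment inits
  per_block <- tr |>
    dplyr::group_by(block_index) |>
    dplyr::group_map(~ dc_nll(dplyr::mutate(.x, block_index = .y$block_index),
                              p, model_variant("m4"), policy = pol))
  num <- sum(vapply(per_block, function(r) r$nll * r$n_trials, numeric(1)))
  den <- sum(vapply(per_block, function(r) r$n_trials, numeric(1)))
  expect_equal(whole$nll, num / den, tolerance = 1e-12)
  expect_equal(whole$n_trials, den)
})

test_that("RL steps and value updates follow the prediction-error rule", {
  p <- rl_params(alpha = 0.2, gamma = 1)
  st <- rl_step(p, list(v_left = 1, v_right = 1), 0.5)
  expect_equal(st$p_right, 0.5)
  # rewarded right with q_right = 0.4: v <- 1 + 0.2 * (1 - 0.4)
  st2 <- rl_update(p, list(v_left = 1, v_right = 1, q_left = 0.4,
                           q_right = 0.4), "right", TRUE)
  expect_equal(st2$v_right, 1.12)
  expect_equal(st2$v_left, 1)   # only the chosen side moves
  st3 <- rl_update(p, list(v_left = 1, v_right = 1, q_left = 0.4,
                           q_right = 0.4), "left", FALSE)
  expect_equal(st3$v_left, 0.92)
  expect_equal(st3$v_right, 1)
})

test_that("RL likelihood equals sequential brute-force evaluation", {
  cfg <- exact_cfg()
  tr <- tiny_trials(sf = cfg$sf_values[c(4, 1, 7, 4, 1)],
                    choice = c("left", "left", "right", "right", "left"),
                    config = cfg)
  expect_equal(rl_nll(tr, rl_params(alpha = 0.35, gamma = 2.2),
                      config = cfg)$nll,
               oracle_rl_nll(tr, 0.35, 2.2), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:8) {
    n <- sample(5:25, 1)
    trr <- tiny_trials(sf = sample(cfg$sf_values, n, replace = TRUE),
                       choice = sample(c("left", "right"), n, replace = TRUE),
                       config = cfg)
    a <- runif(1, 0.05, 0.95); g <- runif(1, 0.2, 5)
    expect_equal(rl_nll(trr, rl_params(a, g), config = cfg)$nll,
                 oracle_rl_nll(trr, a, g), tolerance = 1e-10)
  }
})

test_that("parameter vectors respect family constraints and variant masks", {
  expect_error(dc_params(gamma1 = -0.5), "gamma1")
  expect_error(dc_params(beta = 1.2), "beta")
  expect_error(rl_params(alpha = 0), "alpha")
  expect_error(rl_params(alpha = 1), "alpha")
  v4 <- model_variant("m4")
  expect_identical(sort(v4$free), c("beta", "gamma1", "gamma2"))
  expect_error(check_params(dc_params(alpha1 = 0.2), v4), "fixes")
  expect_identical(length(model_variant("rl")$free), 2L)
  # serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_params(medians_m1(), model_variant("m1"), path)
  back <- read_params(path)
  expect_equal(back$params, medians_m1())
  expect_identical(back$variant$id, "m1")
})
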