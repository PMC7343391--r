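test_that("ROC preference matches the exhaustive all-pairs oracle", {
  expect_equal(roc_preference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(roc_preference(c(1, 2), c(2, 3)), 0.75)  # 3.5 of 4 pairs
  expect_equal(roc_preference(c(0, 1), c(5, 6)), 1)     # full separation
  expect_equal(roc_preference(c(5, 6), c(0, 1)), -1)
  expect_error(roc_preference(numeric(0), 1), "nonempty")
  # property: rank form equals brute force on random tied count data
  set.seed(19)
  for (i in 1:30) {
    a <- rpois(sample(2:12, 1), 3)
    b <- rpois(sample(2:12, 1), 4)
    expect_equal(roc_preference(a, b), oracle_roc_preference(a, b))
    # antisymmetry
    expect_equal(roc_preference(a, b), -roc_preference(b, a))
  }
})

test_that("synthetic spike tables have the constructed tuning structure", {
  tab <- synth_spike_table(n_neurons = 80L, n_trials = 300L, seed = 23L)
  expect_identical(dim(tab$counts), c(80L, 300L))
  expect_true(all(tab$counts >= 0))
  expect_identical(tab$counts, synth_spike_table(n_neurons = 80L,
                                                 n_trials = 300L,
                                                 seed = 23L)$counts)
  # no choice tuning -> choice preferences concentrate near zero
  flat <- synth_spike_table(n_neurons = 60L, n_trials = 400L,
                            choice_gain = 0, history_gain = 0.5, seed = 29L)
  prefs <- vapply(seq_len(60L), function(n) {
    roc_preference(flat$counts[n, flat$labels$choice == "left"],
                   flat$counts[n, flat$labels$choice == "right"])
  }, numeric(1))
  expect_lt(mean(abs(prefs)), 0.08)
  # coupled loadings induce correlated choice/history preferences
  coup <- synth_spike_table(n_neurons = 100L, n_trials = 400L,
                            choice_gain = 0.5, history_gain = 0.5,
                            coupling = 0.9, seed = 31L)
  pc <- vapply(seq_len(100L), function(n) {
    roc_preference(coup$counts[n, coup$labels$choice == "left"],
                   coup$counts[n, coup$labels$choice == "right"])
  }, numeric(1))
  ph <- vapply(seq_len(100L), function(n) {
    roc_preference(coup$counts[n, coup$labels$prev_stim_class == "low"],
                   coup$counts[n, coup$labels$prev_stim_class == "high"])
  }, numeric(1))
  expect_gt(abs(cor(pc, ph)), 0.6)
})

test_that("inclusion criteria drop low-rate and under-sampled neurons", {
  tab <- synth_spike_table(n_neurons = 20L, n_trials = 400L,
                           base_rate = 5, seed = 37L)
  # neuron 1: silence it everywhere -> fails the 0.5 spikes/s floor
  dur_s <- diff(tab$window) / 1000
  tab$counts[1, ] <- rpois(400L, 0.4 * dur_s * 0.5)  # ~0.2 spikes/s
  # neuron 2: mask most trials -> fails the 10-per-class floor
  tab$counts[2, 13:400] <- NA_integer_
  inc <- apply_inclusion(tab, target = "choice")
  expect_false(1L %in% inc$neurons)
  expect_false(2L %in% inc$neurons)
  expect_true(all(3:20 %in% inc$neurons))
  expect_identical(inc$n_excluded, 2L)
  # rate just above threshold in one condition is enough
  tab2 <- synth_spike_table(n_neurons = 5L, n_trials = 400L,
                            base_rate = 5, seed = 41L)
  tab2$counts[3, ] <- 0L
  stable_rows <- which(tab2$labels$period == "stable" & tab2$labels$correct)
  tab2$counts[3, stable_rows] <- rpois(length(stable_rows), 0.6 * dur_s)
  inc2 <- apply_inclusion(tab2, target = "choice")
  expect_true(3L %in% inc2$neurons)
})

test_that("pseudopopulation decoding separates tuned classes and not shuffles", {
  cfg <- decode_config(n_trials_per_class = 10L, n_resamples = 20L,
                       cv_repeats = 10L, seed = 43L)
  strong <- synth_spike_table(n_neurons = 40L, n_trials = 200L,
                              choice_gain = 1.0, history_gain = 0,
                              seed = 47L)
  acc <- pseudopopulation_decode(strong, target = "choice", cfg = cfg)
  expect_identical(nrow(acc), 20L)
  expect_gt(mean(acc$accuracy), 0.9)
  # seed-fixed determinism
  acc2 <- pseudopopulation_decode(strong, target = "choice", cfg = cfg)
  expect_identical(acc, acc2)
  # shuffling labels destroys the code: accuracy at chance
  shuf <- strong
  set.seed(49)
  shuf$labels$choice <- sample(shuf$labels$choice)
  acc0 <- pseudopopulation_decode(shuf, target = "choice", cfg = cfg)
  n_eff <- 20L * 5L  # resamples x held-out pseudotrials
  expect_lt(abs(mean(acc0$accuracy) - 0.5), 3 * sqrt(0.25 / n_eff))
})

test_that("sliding windows tile the span and track a tuning onset", {
  # 50 ms bins stepped 25 ms across 0-900 ms: 35 bins
  spikes <- synth_binned_spikes(n_neurons = 25L, n_trials = 150L,
                                choice_gain = 0.8, onset_ms = 400,
                                seed = 53L)
  expect_identical(length(spikes$starts), 35L)
  pref_fun <- function(m, center) {
    left <- spikes$labels$choice == "left"
    tibble::tibble(mean_abs_pref = mean(vapply(seq_len(nrow(m)), function(n) {
      abs(roc_preference(m[n, left], m[n, !left]))
    }, numeric(1))))
  }
  res <- sliding_window(spikes$array, pref_fun)
  expect_identical(nrow(res), 35L)
  expect_identical(res$bin_center, spikes$starts + 25)
  pre <- res$mean_abs_pref[res$bin_center < 400]
  post <- res$mean_abs_pref[res$bin_center >= 400]
  expect_gt(mean(post), mean(pre) + 0.1)
  # a constant-rate population carries no preference anywhere
  flat <- synth_binned_spikes(n_neurons = 25L, n_trials = 150L,
                              choice_gain = 0, seed = 59L)
  res0 <- sliding_window(flat$array, function(m, center) {
    left <- flat$labels$choice == "left"
    tibble::tibble(mean_pref = mean(vapply(seq_len(nrow(m)), function(n) {
      roc_preference(m[n, left], m[n, !left])
    }, numeric(1))))
  })
  expect_lt(max(abs(res0$mean_pref)), 0.15)
  # bins that would extend past the span are dropped; a span that does not
  # tile exactly is flagged
  arr <- flat$array
  expect_identical(nrow(sliding_window(arr, function(m, c) 1,
                                       span = c(0, 100))), 3L)
  expect_warning(short <- sliding_window(arr, function(m, c) 1,
                                         span = c(0, 90)), "trimmed")
  expect_identical(nrow(short), 2L)
})
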