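test_that("psychometric fitting recovers a noiseless generating curve", {
  x <- log(task_config()$sf_values)
  truth <- list(lapse_low = 0, lapse_high = 0,
                threshold = mean(range(x)), slope = 0.3)
  p <- flexcat:::psy_fun(x, truth$lapse_low, truth$lapse_high,
                         truth$threshold, truth$slope)
  # expected counts at large n make the binomial MLE land on the truth
  counts <- tibble::tibble(x = x, n_total = 1e6, n_right = 1e6 * p)
  fit <- fit_psychometric(counts)
  expect_equal(fit$threshold, truth$threshold, tolerance = 1e-3)
  expect_equal(fit$slope, truth$slope, tolerance = 1e-2)
  expect_lt(fit$lapse_low, 1e-3)
  expect_lt(fit$lapse_high, 1e-3)
  # midpoint identity of the 4-parameter form
  expect_equal(
    flexcat:::psy_fun(fit$threshold, fit$lapse_low, fit$lapse_high,
                      fit$threshold, fit$slope),
    fit$lapse_low + (1 - fit$lapse_low - fit$lapse_high) / 2
  )
  td <- tidy(fit)
  expect_identical(td$term, c("lapse_low", "lapse_high", "threshold", "slope"))
})

test_that("psychometric threshold is equivariant to shifts of the axis", {
  set.seed(3)
  x <- log(task_config()$sf_values)
  p <- flexcat:::psy_fun(x, 0.05, 0.03, mean(x), 0.25)
  n <- 2000
  counts <- tibble::tibble(x = x, n_total = n, n_right = rbinom(7, n, p))
  f1 <- fit_psychometric(counts)
  shift <- 1.7
  f2 <- fit_psychometric(dplyr::mutate(counts, x = x + shift))
  expect_equal(f2$threshold, f1$threshold + shift, tolerance = 1e-4)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-4)
})

test_that("degenerate all-one-side data raise the boundary-at-infinity flag", {
  x <- log(task_config()$sf_values)
  fit <- fit_psychometric(tibble::tibble(x = x, n_total = 50, n_right = 0))
  expect_true(fit$degenerate)
  expect_identical(fit$threshold, Inf)
  expect_error(fit_psychometric(tibble::tibble(x = x[1:3], n_total = 10,
                                               n_right = 5)),
               "4 distinct")
})

test_that("trials to reverse choice matches the closed form and a root-finder", {
  n_rev <- trials_to_reverse(A = 0.6, tau = 5, I = 0.2)
  expect_equal(n_rev, -5 * log(0.5), tolerance = 1e-12)
  # agreement with a numeric root of f(n) = 0.5 to 1e-9
  root <- stats::uniroot(function(n) 0.6 * (1 - exp(-n / 5)) + 0.2 - 0.5,
                         c(0, 100), tol = 1e-12)$root
  expect_equal(n_rev, root, tolerance = 1e-9)
  # boundary case: already at 50% before the switch
  expect_warning(flag <- trials_to_reverse(A = 0.5, tau = 5, I = 0.5),
                 "does not cross")
  expect_true(is.na(flag))
})

test_that("the exponential reversal fit recovers known dynamics", {
  set.seed(11)
  n <- 1:60
  truth <- c(A = 0.62, tau = 6, I = 0.18)
  curve <- tibble::tibble(
    n = n,
    correct_rate = truth["A"] * (1 - exp(-n / truth["tau"])) + truth["I"] +
      rnorm(60, 0, 0.01)
  )
  fit <- fit_reversal(curve)
  expect_equal(fit$A, unname(truth["A"]), tolerance = 0.05)
  expect_equal(fit$tau, unname(truth["tau"]), tolerance = 0.15)
  expect_equal(fit$I, unname(truth["I"]), tolerance = 0.05)
  expect_true(fit$crossing_defined)
  expect_equal(fit$n_reverse,
               trials_to_reverse(fit$A, fit$tau, fit$I), tolerance = 1e-12)
})

test_that("a simulated adaptive agent reverses in finitely many trials", {
  tr <- sim_small(n_blocks = 15L, seed = 71L)
  curve <- reversal_curve(tr)
  expect_true(all(curve$n >= 1 & curve$n <= 60))
  fit <- fit_reversal(curve)
  expect_true(fit$crossing_defined)
  expect_gt(fit$n_reverse, 0)
  expect_lt(fit$n_reverse, 30)
})

test_that("right-choice bias matches hand enumeration on a tiny session", {
  cfg <- exact_cfg()
  sfs <- cfg$sf_values
  # low block: reversing trials at positions 2, 4, 6, 8 (1-based), preceded
  # by low (SF1), low (SF2), high (SF7), reversing; then a high block whose
  # reversing trials are preceded by reversing, high (SF7), low (SF1)
  sf <- c(sfs[c(1, 4, 2, 4, 7, 4, 4, 4)], sfs[c(4, 7, 4, 1, 4)])
  ch <- c("left", "right", "left", "right", "right", "left", "left", "right",
          "left", "right", "left", "left", "right")
  tr <- fc_trials("s1", rep(0:1, c(8L, 5L)), rep(c("low", "high"), c(8L, 5L)),
                  sf, ch, config = cfg)
  got <- right_choice_bias(tr, period = "all")
  # low block: 5 reversing trials, right on 1, 1, 0, 0, 1
  base_low <- mean(c(1, 1, 0, 0, 1))
  # high block: 3 reversing trials (positions 9, 11, 13), right on 0, 0, 1
  base_high <- mean(c(0, 0, 1))
  expect_equal(got$bias_after_low, mean(c(1, 1)) - base_low)  # after SF1, SF2
  expect_equal(got$bias_after_high, mean(c(0)) - base_high)   # after SF7
  expect_equal(got$difference, got$bias_after_low - got$bias_after_high)
  expect_identical(got$n_after_low, 2L)
  expect_identical(got$n_after_high, 1L)
  expect_identical(got$n_base_low, 5L)
  expect_identical(got$n_base_high, 3L)
})

test_that("bias difference is antisymmetric under global left/right flips", {
  tr <- sim_small(n_blocks = 6L, seed = 73L)
  flip <- tr |>
    dplyr::mutate(
      choice = ifelse(choice == "left", "right", "left"),
      block_type = ifelse(block_type == "low", "high", "low"),
      sf_norm = -sf_norm,
      rewarded = choice == correct_side(sf_norm, block_type)
    )
  a <- right_choice_bias(tr, "switching")
  b <- right_choice_bias(flip, "switching")
  # the two conditional biases swap with a sign change, so the
  # after-low-minus-after-high difference is preserved by the mirror
  expect_equal(b$bias_after_low, -a$bias_after_high, tolerance = 1e-12)
  expect_equal(b$bias_after_high, -a$bias_after_low, tolerance = 1e-12)
  expect_equal(b$difference, a$difference, tolerance = 1e-12)
  # flipping the choice labels alone negates both biases and the difference
  anti <- dplyr::mutate(tr, choice = ifelse(choice == "left", "right", "left"))
  d <- right_choice_bias(anti, "switching")
  expect_equal(d$difference, -a$difference, tolerance = 1e-12)
})

test_that("the steady-state filter drops early post-switch trials", {
  tr <- sim_small(n_blocks = 4L, seed = 79L)
  counts <- psychometric_counts(tr, exclude_after_switch = 30L)
  kept <- tr |>
    dplyr::filter(block_index == 0L | trial_in_block >= 30L)
  expect_identical(sum(counts$n_total), nrow(kept))
  expect_identical(nrow(counts), 7L)
  low_only <- psychometric_counts(tr, block_type = "low")
  expect_lte(sum(low_only$n_total), sum(counts$n_total))
})
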