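#' Configure the boundary-switching categorization task
#'
#' A task configuration captures the stimulus set and the block/switch rules
#' of the flexible categorization task: seven log-spaced spatial frequencies,
#' of which the middle one is the *reversing stimulus* whose correct response
#' flips between low-boundary and high-boundary blocks; blocks run for at
#' least `min_block_trials` trials and end once performance for the reversing
#' stimulus over the last `switch_window` reversing-stimulus trials reaches
#' `switch_criterion`.
#'
#' @param sf_values Strictly increasing numeric vector of 7 spatial
#'   frequencies (cycles/degree). The default is the primary stimulus set
#'   (0.03--0.3 cycles/degree); the alternative 0.06--0.2 set is expressed by
#'   passing its values here, no code path special-cases either set.
#' @param frequent_prob Total probability mass on the two block-frequent
#'   stimuli (default 0.90).
#' @param min_block_trials Minimum number of trials per block (default 60).
#' @param switch_window Number of most recent reversing-stimulus trials over
#'   which the switch criterion is evaluated (default 10).
#' @param switch_criterion Fraction correct for the reversing stimulus that
#'   triggers a boundary switch (default 0.70; some cohorts used 0.80).
#' @param period_length Number of trials in the stable (pre-switch) and
#'   switching (post-switch) periods (default 15).
#' @param max_block_trials Safety cap on block length during simulation; a
#'   block is force-switched (and counted) once it exceeds this many trials.
#'
#' @return An object of class `task_config` (a list).
#' @examples
#' cfg <- task_config()
#' normalize_sf(cfg$sf_values, cfg)
#' @export
task_config <- function(sf_values = c(0.03, 0.044, 0.065, 0.095, 0.139, 0.204, 0.3),
                        frequent_prob = 0.90,
                        min_block_trials = 60L,
                        switch_window = 10L,
                        switch_criterion = 0.70,
                        period_length = 15L,
                        max_block_trials = 500L) {
  stopifnot(
    is.numeric(sf_values), length(sf_values) == 7L, all(sf_values > 0),
    all(diff(sf_values) > 0),
    frequent_prob > 0, frequent_prob < 1,
    min_block_trials >= 1, switch_window >= 1,
    switch_criterion > 0, switch_criterion < 1,
    period_length >= 1, period_length <= min_block_trials,
    max_block_trials >= min_block_trials
  )
  # the reversing stimulus is the geometric middle of a log-spaced set
  lr <- log(sf_values)
  ratios <- diff(lr)
  if (max(abs(ratios - mean(ratios))) > 0.15 * abs(mean(ratios))) {
    warning("sf_values deviate noticeably from exact log spacing")
  }
  structure(
    list(
      sf_values = as.numeric(sf_values),
      reversing_index = 4L,
      frequent_prob = frequent_prob,
      min_block_trials = as.integer(min_block_trials),
      switch_window = as.integer(switch_window),
      switch_criterion = switch_criterion,
      period_length = as.integer(period_length),
      max_block_trials = as.integer(max_block_trials)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat("  sf_values (c/deg): ", paste(signif(x$sf_values, 3), collapse = ", "), "\n")
  cat("  reversing stimulus: SF", x$reversing_index,
      " = ", x$sf_values[x$reversing_index], " c/deg\n", sep = "")
  cat("  block rule: >=", x$min_block_trials, " trials and >=",
      round(100 * x$switch_criterion), "% correct over last ",
      x$switch_window, " reversing-stimulus trials\n", sep = "")
  invisible(x)
}

#' Normalize spatial frequency onto the signed model scale
#'
#' Maps a stimulus spatial frequency onto a dimensionless value in
#' \[-1, 1\]: negative for frequencies below the reversing stimulus,
#' positive above it, and exactly 0 for the reversing stimulus. The map is
#' linear in log frequency, `(log sf - log sf_rev) / (log sf_max - log
#' sf_rev)`, so an exactly log-spaced 7-stimulus set lands on
#' \{-1, -2/3, -1/3, 0, 1/3, 2/3, 1\}.
#'
#' @param sf Numeric vector of spatial frequencies; every element must be one
#'   of `config$sf_values`.
#' @param config A [task_config()].
#' @return Numeric vector in \[-1, 1\].
#' @seealso [normalize_sf01()] for the \[0, 1\] convention used by the
#'   reinforcement-learning model.
#' @export
normalize_sf <- function(sf, config = task_config()) {
  idx <- match_sf(sf, config)
  lr <- log(config$sf_values)
  rev <- lr[config$reversing_index]
  (lr[idx] - rev) / (lr[length(lr)] - rev)
}

#' Normalize spatial frequency onto the unit interval
#'
#' The reinforcement-learning model weighs choice values by the stimulus
#' normalized between 0 (lowest frequency) and 1 (highest frequency), linear
#' in log frequency.
#'
#' @inheritParams normalize_sf
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_sf01 <- function(sf, config = task_config()) {
  idx <- match_sf(sf, config)
  lr <- log(config$sf_values)
  (lr[idx] - lr[1L]) / (lr[length(lr)] - lr[1L])
}

# match sf against the configured set with a relative tolerance; error on miss
match_sf <- function(sf, config) {
  idx <- vapply(sf, function(f) {
    hit <- which(abs(config$sf_values - f) <= 1e-8 * max(f, 1e-12))
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(idx)) {
    bad <- unique(sf[is.na(idx)])
    stop("invalid stimulus: sf not in the configured set: ",
         paste(signif(bad, 4), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Correct response side for a stimulus in a given block type
#'
#' The rewarded side is left when the stimulus frequency is below the
#' block's category boundary and right when above it. In low-boundary blocks
#' the boundary sits just below the reversing stimulus (so the reversing
#' stimulus is "high", correct side right); in high-boundary blocks it sits
#' just above (correct side left).
#'
#' @param sf_norm Numeric vector in \[-1, 1\], the signed normalized stimulus
#'   (see [normalize_sf()]).
#' @param block_type Character vector, `"low"` or `"high"` (recycled).
#' @return Character vector of `"left"` / `"right"`.
#' @export
correct_side <- function(sf_norm, block_type) {
  # sets that are only approximately log-spaced can overshoot +-1 slightly
  stopifnot(all(sf_norm >= -1.05 & sf_norm <= 1.05))
  block_type <- check_block_type(block_type)
  n <- max(length(sf_norm), length(block_type))
  sf_norm <- rep_len(sf_norm, n)
  block_type <- rep_len(block_type, n)
  ifelse(block_type == "low",
         ifelse(sf_norm >= 0, "right", "left"),
         ifelse(sf_norm <= 0, "left", "right"))
}

check_block_type <- function(block_type) {
  block_type <- as.character(block_type)
  if (!all(block_type %in% c("low", "high"))) {
    stop("block_type must be 'low' or 'high'", call. = FALSE)
  }
  block_type
}
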