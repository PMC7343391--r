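#' ROC preference between two response distributions
#'
#' The area under the ROC curve is computed exactly in its rank
#' (Mann-Whitney) form -- the probability that a random draw from `b`
#' exceeds one from `a`, ties counted one half -- and mapped to the signed
#' preference `2 * (auROC - 0.5)` in \[-1, 1\]. With `a` the left-choice
#' (or previous-low-stimulus) responses and `b` the right-choice (or
#' previous-high) responses, positive values mean higher firing for right
#' choices (previous-high stimuli).
#'
#' @param a,b Nonempty numeric vectors of spike counts (or rates).
#' @return Scalar preference in \[-1, 1\].
#' @export
roc_preference <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both response groups must be nonempty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))                 # midranks handle ties exactly
  auroc <- (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
  2 * (auroc - 0.5)
}

#' Synthetic spike-count table with choice and history tuning
#'
#' Generates Poisson spike counts for a population of independently
#' "recorded" neurons with log-linear tuning to the upcoming choice and the
#' previous stimulus class:
#' `log rate_i(t) = log(base) + choice_gain * c_i * x_choice(t) +
#' history_gain * h_i * x_prev(t)`, with `x` the +-1 trial labels and the
#' per-neuron loadings `(c_i, h_i)` standard bivariate normal with
#' correlation `coupling` -- so across neurons the choice preference and
#' previous-stimulus preference correlate by construction, emulating the
#' coupled choice/history coding observed in premotor populations. Trials
#' are all reversing-stimulus trials; period and correctness labels are
#' assigned independently.
#'
#' @param n_neurons,n_trials Population and per-neuron trial counts.
#' @param base_rate Baseline firing rate (spikes/s).
#' @param choice_gain,history_gain Nonnegative tuning gains (log-rate units
#'   per label unit).
#' @param coupling Correlation of the two loadings, in \[-1, 1\].
#' @param window Analysis window (start, end) in ms after trial initiation.
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return An object of class `spike_table`: list with `counts` (neuron x
#'   trial integer matrix), `labels` (tibble: `trial`, `choice`,
#'   `prev_stim_class`, `period`, `correct`), `window` (ms), `rate`
#'   (per-neuron mean rate, spikes/s), `loadings` (tibble: `choice_loading`,
#'   `history_loading`).
#' @export
synth_spike_table <- function(n_neurons = 50L, n_trials = 200L,
                              base_rate = 5, choice_gain = 0.4,
                              history_gain = 0.4, coupling = 0,
                              window = c(0, 700), seed = 1L) {
  stopifnot(choice_gain >= 0, history_gain >= 0,
            coupling >= -1, coupling <= 1, base_rate > 0,
            window[2] > window[1])
  set.seed(seed)
  z1 <- stats::rnorm(n_neurons)
  z2 <- stats::rnorm(n_neurons)
  c_load <- z1
  h_load <- coupling * z1 + sqrt(1 - coupling^2) * z2
  x_choice <- sample(c(-1, 1), n_trials, replace = TRUE)
  x_prev <- sample(c(-1, 1), n_trials, replace = TRUE)
  dur_s <- diff(window) / 1000
  lograte <- log(base_rate) +
    outer(choice_gain * c_load, x_choice) +
    outer(history_gain * h_load, x_prev)
  counts <- matrix(
    stats::rpois(n_neurons * n_trials, exp(lograte) * dur_s),
    nrow = n_neurons
  )
  rownames(counts) <- paste0("n", seq_len(n_neurons))
  labels <- tibble::tibble(
    trial = seq_len(n_trials),
    choice = ifelse(x_choice > 0, "right", "left"),
    prev_stim_class = ifelse(x_prev > 0, "high", "low"),
    period = sample(c("stable", "switching"), n_trials, replace = TRUE),
    correct = sample(c(TRUE, FALSE), n_trials, replace = TRUE,
                     prob = c(0.8, 0.2))
  )
  structure(
    list(counts = counts, labels = labels, window = window,
         rate = rowMeans(counts) / dur_s,
         loadings = tibble::tibble(choice_loading = c_load,
                                   history_loading = h_load)),
    class = "spike_table"
  )
}

#' @export
print.spike_table <- function(x, ...) {
  cat("<spike_table> ", nrow(x$counts), " neurons x ", ncol(x$counts),
      " trials, window ", x$window[1], "-", x$window[2], " ms\n", sep = "")
  invisible(x)
}

label_column <- function(target) {
  switch(target, choice = "choice", prev_stim = "prev_stim_class",
         stop("target must be 'choice' or 'prev_stim'", call. = FALSE))
}

# trials of the table belonging to an analysis condition
condition_trials <- function(table, period = NULL, correct = NULL) {
  keep <- rep(TRUE, nrow(table$labels))
  if (!is.null(period)) keep <- keep & table$labels$period == period
  if (!is.null(correct)) keep <- keep & table$labels$correct == correct
  which(keep)
}

#' Neuron inclusion criteria for selectivity and decoding
#'
#' A neuron is kept when it has at least `min_trials` trials of each class
#' of the target label under each condition, and a firing rate above
#' `min_rate` spikes/s in at least one condition.
#'
#' @param table A `spike_table`.
#' @param target `"choice"` or `"prev_stim"`.
#' @param conditions List of conditions, each a list with `period` and/or
#'   `correct` entries (default: the four period x correctness cells).
#' @param min_trials Per-class trial threshold (default 10).
#' @param min_rate Firing-rate threshold in spikes/s (default 0.5).
#' @return A list with `neurons` (indices kept), `n_excluded`, and
#'   `per_neuron` (tibble of the per-neuron checks).
#' @export
apply_inclusion <- function(table, target = "choice",
                            conditions = NULL,
                            min_trials = 10L, min_rate = 0.5) {
  col <- label_column(target)
  if (is.null(conditions)) {
    conditions <- list(
      list(period = "stable", correct = TRUE),
      list(period = "stable", correct = FALSE),
      list(period = "switching", correct = TRUE),
      list(period = "switching", correct = FALSE)
    )
  }
  dur_s <- diff(table$window) / 1000
  n_neurons <- nrow(table$counts)
  enough <- rep(TRUE, n_neurons)
  rate_ok <- rep(FALSE, n_neurons)
  for (cond in conditions) {
    idx <- condition_trials(table, cond$period, cond$correct)
    cls <- table$labels[[col]][idx]
    min_class <- if (length(idx) == 0) 0L else min(table(factor(cls)))
    if (length(unique(cls)) < 2L) min_class <- 0L
    # trial counts are shared across neurons here because a synthetic table
    # has every neuron on every trial; recorded tables subset per neuron by
    # NA counts
    for (n in seq_len(n_neurons)) {
      have <- idx[!is.na(table$counts[n, idx])]
      cls_n <- table$labels[[col]][have]
      tab <- table(factor(cls_n, levels = unique(table$labels[[col]])))
      if (length(tab) < 2L || min(tab) < min_trials) enough[n] <- FALSE
      if (length(have) > 0 &&
          mean(table$counts[n, have], na.rm = TRUE) / dur_s > min_rate) {
        rate_ok[n] <- TRUE
      }
    }
  }
  keep <- which(enough & rate_ok)
  list(neurons = keep, n_excluded = n_neurons - length(keep),
       per_neuron = tibble::tibble(neuron = seq_len(n_neurons),
                                   enough_trials = enough,
                                   rate_ok = rate_ok))
}

#' Decoding configuration
#'
#' @param n_trials_per_class Trials sampled (without replacement) per class
#'   per neuron to build a pseudopopulation (default 10).
#' @param n_resamples Number of pseudopopulation resamples (the full
#'   protocol uses 1500; 100 for sliding windows).
#' @param cv_repeats Train/test repetitions per resample (default 100).
#' @param train_fraction Fraction of pseudotrials used for training
#'   (default 0.75).
#' @param seed Integer seed.
#' @return A `decode_config` object.
#' @export
decode_config <- function(n_trials_per_class = 10L, n_resamples = 1500L,
                          cv_repeats = 100L, train_fraction = 0.75,
                          seed = 1L) {
  stopifnot(n_trials_per_class >= 2, train_fraction > 0, train_fraction < 1,
            n_resamples >= 1, cv_repeats >= 1)
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_resamples = as.integer(n_resamples),
                 cv_repeats = as.integer(cv_repeats),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "decode_config")
}

#' Pseudopopulation decoding of choice or sensory history
#'
#' For each resample, `n_trials_per_class` trials per class are drawn
#' without replacement independently per neuron to assemble a
#' pseudopopulation matrix; a linear support-vector classifier (cost 1) is
#' then trained on `train_fraction` of the pseudotrials and tested on the
#' rest, `cv_repeats` times; features are z-scored using training-split
#' statistics only. The mean test accuracy per resample is returned.
#'
#' @param table A `spike_table`.
#' @param target `"choice"` or `"prev_stim"`.
#' @param period,correct Condition restriction (NULL = no restriction).
#' @param cfg A [decode_config()].
#' @param neurons Optional neuron indices (default: all passing
#'   [apply_inclusion()] for this condition).
#' @return A tibble with `resample` and `accuracy` (`cfg$n_resamples` rows).
#' @export
pseudopopulation_decode <- function(table, target = "choice",
                                    period = NULL, correct = NULL,
                                    cfg = decode_config(), neurons = NULL) {
  col <- label_column(target)
  if (is.null(neurons)) {
    conds <- list(list(period = period, correct = correct))
    neurons <- apply_inclusion(table, target, conditions = conds,
                               min_trials = cfg$n_trials_per_class)$neurons
  }
  if (length(neurons) == 0) stop("no neurons pass inclusion", call. = FALSE)
  idx <- condition_trials(table, period, correct)
  classes <- sort(unique(table$labels[[col]]))
  stopifnot(length(classes) == 2L)
  by_class <- lapply(classes, function(cl) {
    idx[table$labels[[col]][idx] == cl]
  })
  short <- vapply(by_class, length, integer(1)) < cfg$n_trials_per_class
  if (any(short)) {
    stop("fewer than ", cfg$n_trials_per_class, " trials for class ",
         paste(classes[short], collapse = ", "), call. = FALSE)
  }
  set.seed(cfg$seed)
  ntpc <- cfg$n_trials_per_class
  y <- factor(rep(classes, each = ntpc))
  n_pseudo <- 2L * ntpc
  n_train <- max(1L, round(cfg$train_fraction * n_pseudo))
  acc <- numeric(cfg$n_resamples)
  for (r in seq_len(cfg$n_resamples)) {
    X <- matrix(0, n_pseudo, length(neurons))
    for (j in seq_along(neurons)) {
      X[, j] <- c(
        table$counts[neurons[j], sample(by_class[[1]], ntpc)],
        table$counts[neurons[j], sample(by_class[[2]], ntpc)]
      )
    }
    reps <- numeric(cfg$cv_repeats)
    for (cvr in seq_len(cfg$cv_repeats)) {
      tr <- sort(sample.int(n_pseudo, n_train))
      te <- setdiff(seq_len(n_pseudo), tr)
      if (length(unique(y[tr])) < 2L || length(te) == 0L) {
        reps[cvr] <- NA_real_
        next
      }
      mu <- colMeans(X[tr, , drop = FALSE])
      sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0 | !is.finite(sd_)] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd_, "/")
      if (r == 1L && cvr == 1L) {
        # standardization sanity: training features centered and unit-scaled
        stopifnot(all(abs(colMeans(Xtr)) < 1e-8),
                  all(abs(apply(Xtr, 2, stats::sd) - 1) < 1e-8 |
                        apply(Xtr, 2, stats::sd) == 0))
      }
      mod <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = 1,
                        scale = FALSE)
      reps[cvr] <- mean(stats::predict(mod, Xte) == y[te])
    }
    acc[r] <- mean(reps, na.rm = TRUE)
  }
  tibble::tibble(resample = seq_len(cfg$n_resamples), accuracy = acc)
}

#' Sliding-window analysis of binned spike counts
#'
#' Applies a per-bin analysis over 50 ms bins stepped by 25 ms across an
#' analysis span (default 0--900 ms after trial initiation), the bin time
#' stamped at the bin center. Bins extending past the span are trimmed with
#' a warning.
#'
#' @param bin_counts A 3-d array `neuron x trial x bin` of spike counts,
#'   with `dimnames[[3]]` the bin start times in ms, or a function
#'   `(start, end) -> neuron x trial matrix` evaluated per bin.
#' @param fun Per-bin analysis: a function `(counts_matrix, bin_center)`
#'   returning a scalar or one-row data frame.
#' @param span Analysis span in ms.
#' @param bin,step Bin width and step in ms.
#' @return A tibble with `bin_start`, `bin_center` and the per-bin results.
#' @export
sliding_window <- function(bin_counts, fun, span = c(0, 900),
                           bin = 50, step = 25) {
  if (span[2] - span[1] < bin) stop("no bin fits inside the span", call. = FALSE)
  starts <- seq(span[1], span[2] - bin, by = step)
  if ((span[2] - span[1] - bin) %% step != 0) {
    warning("span is not tiled exactly; bin(s) extending past ", span[2],
            " ms were trimmed")
  }
  res <- purrr::map_dfr(starts, function(st) {
    m <- if (is.function(bin_counts)) bin_counts(st, st + bin)
         else bin_counts[, , as.character(st)]
    out <- fun(m, st + bin / 2)
    if (!is.data.frame(out)) out <- tibble::tibble(value = out)
    dplyr::mutate(out, bin_start = st, bin_center = st + bin / 2)
  })
  dplyr::relocate(res, "bin_start", "bin_center")
}

#' Bin spikes of a synthetic session into sliding-window counts
#'
#' Convenience generator for sliding-window tests: draws per-bin Poisson
#' counts with the same tuning structure as [synth_spike_table()], with the
#' tuning switched on only from `onset_ms` onward (emulating a stimulus
#' onset inside the holding period).
#'
#' @inheritParams synth_spike_table
#' @param span Span covered by the bins (ms).
#' @param bin,step Bin geometry (ms).
#' @param onset_ms Time from which the tuning gains apply.
#' @return A list with `array` (`neuron x trial x bin`), `labels`,
#'   `starts`.
#' @export
synth_binned_spikes <- function(n_neurons = 30L, n_trials = 120L,
                                base_rate = 10, choice_gain = 0.6,
                                span = c(0, 900), bin = 50, step = 25,
                                onset_ms = 200, seed = 1L) {
  set.seed(seed)
  starts <- seq(span[1], span[2] - bin, by = step)
  c_load <- stats::rnorm(n_neurons)
  x_choice <- sample(c(-1, 1), n_trials, replace = TRUE)
  arr <- array(0L, dim = c(n_neurons, n_trials, length(starts)),
               dimnames = list(NULL, NULL, as.character(starts)))
  dur_s <- bin / 1000
  for (k in seq_along(starts)) {
    gain <- if (starts[k] + bin / 2 >= onset_ms) choice_gain else 0
    lograte <- log(base_rate) + outer(gain * c_load, x_choice)
    arr[, , k] <- matrix(stats::rpois(n_neurons * n_trials,
                                      exp(lograte) * dur_s),
                         nrow = n_neurons)
  }
  list(array = arr,
       labels = tibble::tibble(trial = seq_len(n_trials),
                               choice = ifelse(x_choice > 0, "right", "left")),
       starts = starts)
}
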