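#' Assemble a trial table
#'
#' Builds the canonical trial tibble from raw per-trial vectors, recomputing
#' every derived column (normalized stimulus values, reversing flag, reward
#' consistency, period labels). All analysis and fitting functions in the
#' package consume this table.
#'
#' @param session_id Session identifier (coerced to character).
#' @param block_index 0-based block index within session.
#' @param block_type `"low"` / `"high"` block label.
#' @param sf Stimulus spatial frequency (cycles/degree), each a member of
#'   `config$sf_values`.
#' @param choice `"left"` / `"right"`.
#' @param rewarded Logical (or 0/1). Must equal `choice == correct_side(...)`
#'   on every trial; violations are an error because in this task reward is a
#'   deterministic function of stimulus, block and choice.
#' @param config A [task_config()].
#'
#' @return A tibble of class `fc_trials` with columns `session_id`,
#'   `block_index`, `block_type`, `trial_in_block` (0-based), `sf`,
#'   `sf_norm`, `sf_norm01`, `is_reversing`, `choice`, `rewarded`, `period`.
#' @export
fc_trials <- function(session_id, block_index, block_type, sf, choice,
                      rewarded = NULL, config = task_config()) {
  n <- length(sf)
  session_id <- rep_len(as.character(session_id), n)
  block_index <- rep_len(as.integer(block_index), n)
  block_type <- check_block_type(rep_len(block_type, n))
  choice <- as.character(choice)
  if (!all(choice %in% c("left", "right"))) {
    stop("choice must be 'left' or 'right'", call. = FALSE)
  }
  sf_norm <- normalize_sf(sf, config)
  expected_reward <- choice == correct_side(sf_norm, block_type)
  if (is.null(rewarded)) {
    rewarded <- expected_reward
  } else {
    rewarded <- as.logical(as.integer(rewarded))
    bad <- which(rewarded != expected_reward)
    if (length(bad) > 0) {
      stop("rewarded flag inconsistent with the correct side at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "", call. = FALSE)
    }
  }
  trials <- tibble::tibble(
    session_id = session_id,
    block_index = block_index,
    block_type = block_type,
    trial_in_block = 0L,
    sf = as.numeric(sf),
    sf_norm = sf_norm,
    sf_norm01 = normalize_sf01(sf, config),
    is_reversing = sf_norm == 0,
    choice = choice,
    rewarded = rewarded,
    period = "other"
  )
  trials <- trials |>
    dplyr::group_by(.data$session_id, .data$block_index) |>
    dplyr::mutate(trial_in_block = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup()
  check_block_structure(trials)
  trials <- label_periods(trials, config)
  class(trials) <- c("fc_trials", class(tibble::tibble()))
  trials
}

# block types must alternate within a session
check_block_structure <- function(trials) {
  blocks <- trials |>
    dplyr::distinct(.data$session_id, .data$block_index, .data$block_type) |>
    dplyr::arrange(.data$session_id, .data$block_index)
  bad <- blocks |>
    dplyr::group_by(.data$session_id) |>
    dplyr::filter(dplyr::n() > 1,
                  any(.data$block_type == dplyr::lag(.data$block_type),
                      na.rm = TRUE)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    stop("block_type must alternate within a session (session ",
         bad$session_id[1], ")", call. = FALSE)
  }
  invisible(trials)
}

#' Label stable and switching periods
#'
#' The last `period_length` trials of every block that is followed by a
#' boundary switch are the *stable* period; the first `period_length` trials
#' of every block that is preceded by a switch are the *switching* period.
#' All other trials (including the opening trials of a session's first block
#' and the tail of its final block) are labelled `"other"`. In blocks shorter
#' than two period lengths the two labels can overlap; switching takes
#' precedence.
#'
#' @param trials A trial tibble (see [fc_trials()]).
#' @param config A [task_config()].
#' @return `trials` with its `period` column recomputed.
#' @export
label_periods <- function(trials, config = task_config()) {
  plen <- config$period_length
  trials |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(.last_block = max(.data$block_index)) |>
    dplyr::group_by(.data$session_id, .data$block_index) |>
    dplyr::mutate(
      .n = dplyr::n(),
      period = dplyr::case_when(
        .data$block_index > 0L & .data$trial_in_block < plen ~ "switching",
        .data$block_index < .data$.last_block &
          .data$trial_in_block >= .data$.n - plen ~ "stable",
        TRUE ~ "other"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".n", -".last_block")
}

#' Read and write trial tables
#'
#' Trial tables are plain UTF-8 CSV files with one row per trial and columns
#' `session_id, block_index, block_type, sf, choice, rewarded` (`rewarded`
#' as 0/1; `block_type` and `choice` as lowercase strings). Derived columns
#' are recomputed on read; any present in the file are ignored. Writing then
#' reading reproduces all fields exactly.
#'
#' @param path File path.
#' @param config A [task_config()] used to validate stimuli and recompute
#'   derived columns.
#' @return `read_trials()` returns an `fc_trials` tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, config = task_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("session_id", "block_index", "block_type", "sf", "choice", "rewarded")
  missing <- setdiff(req, names(raw))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fc_trials(raw$session_id, raw$block_index, raw$block_type, raw$sf,
            raw$choice, raw$rewarded, config = config)
}

#' @param trials A trial tibble (see [fc_trials()]).
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  out <- trials |>
    dplyr::transmute(
      .data$session_id, .data$block_index, .data$block_type, .data$sf,
      .data$choice, rewarded = as.integer(.data$rewarded)
    )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise blocks of a trial table
#'
#' One row per (session, block) with its type, length and whether it is
#' followed by a boundary switch.
#'
#' @param trials A trial tibble.
#' @return A tibble with columns `session_id`, `block_index`, `block_type`,
#'   `n_trials`, `followed_by_switch`.
#' @export
block_summary <- function(trials) {
  trials |>
    dplyr::group_by(.data$session_id, .data$block_index, .data$block_type) |>
    dplyr::summarise(n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(followed_by_switch = .data$block_index < max(.data$block_index)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$session_id, .data$block_index)
}
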