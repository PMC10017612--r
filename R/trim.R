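#' Trimming configuration
#'
#' Thresholds and window lengths of the standard trial- and
#' participant-level cleaning rules: the first two trials of each block are
#' removed; the single trial after an observed error; timeout trials and the
#' two following; fast guesses (RT below `fast_guess_ms`: 300 ms in the
#' laboratory, 100 ms online) and the two following; and, when a
#' `slow_cutoff_ms` is configured (3000 ms, no-response-limit group only),
#' slow responses and the two following. Participants are excluded when
#' their fast-guess rate exceeds `max_fast_guess_rate` of all trials, their
#' error rate exceeds `max_error_rate`, or any analysis cell retains fewer
#' than `min_trials_per_cell` eligible trials.
#'
#' @param fast_guess_ms Fast-guess threshold in ms (RT strictly below is a
#'   fast guess).
#' @param slow_cutoff_ms Slow-response cutoff in ms (strictly above is
#'   removed), or `NULL` to disable.
#' @param post_error_window Trials removed after an error (1).
#' @param timeout_window,fast_guess_window,slow_window Trials removed after
#'   a timeout / fast guess / slow response (2 each).
#' @param min_trials_per_cell Minimum eligible trials per analysis cell (10).
#' @param max_fast_guess_rate Maximum tolerated fast-guess rate (0.10).
#' @param max_error_rate Maximum tolerated error rate (0.33).
#' @return An object of class `trim_config`.
#' @export
trim_config <- function(fast_guess_ms = 300, slow_cutoff_ms = NULL,
                        post_error_window = 1L, timeout_window = 2L,
                        fast_guess_window = 2L, slow_window = 2L,
                        min_trials_per_cell = 10L,
                        max_fast_guess_rate = 0.10, max_error_rate = 0.33) {
  if (fast_guess_ms <= 0) stop("`fast_guess_ms` must be positive")
  if (!is.null(slow_cutoff_ms) && slow_cutoff_ms <= 0)
    stop("`slow_cutoff_ms` must be positive or NULL")
  for (r in c(max_fast_guess_rate, max_error_rate))
    if (r <= 0 || r >= 1) stop("rates must lie in (0, 1)")
  structure(list(fast_guess_ms = fast_guess_ms,
                 slow_cutoff_ms = slow_cutoff_ms,
                 post_error_window = as.integer(post_error_window),
                 timeout_window = as.integer(timeout_window),
                 fast_guess_window = as.integer(fast_guess_window),
                 slow_window = as.integer(slow_window),
                 min_trials_per_cell = as.integer(min_trials_per_cell),
                 max_fast_guess_rate = max_fast_guess_rate,
                 max_error_rate = max_error_rate),
            class = "trim_config")
}

# mark positions t + 1 .. t + w (by trial number, within the same
# participant x block) for every trigger trial t
window_after <- function(trials, trigger, w) {
  out <- logical(nrow(trials))
  if (w < 1L || !any(trigger)) return(out)
  key <- paste(trials$participant, trials$block, sep = "\r")
  idx <- paste(key, trials$trial, sep = "\r")
  for (k in seq_len(w)) {
    hit <- paste(key[trigger], trials$trial[trigger] + k, sep = "\r")
    out[idx %in% hit] <- TRUE
  }
  out
}

#' Apply trial-level trimming
#'
#' Flags every trial with a removal reason and eligibility indicators.
#' Removal windows are defined on within-block trial numbers and never cross
#' block boundaries. A removed trial is ineligible *as trial N* of an
#' analysis, but its raw task, accuracy and RT remain available as N-1/N-2
#' context — without this, analyses conditioned on N-2 errors would be
#' impossible. Error trials themselves receive the reason `error_rt_only`:
#' they stay eligible for accuracy/MPT tabulations but are excluded as
#' targets of RT analyses.
#'
#' @param trials Trial table with `participant`, `block`, `trial`,
#'   `rt_ms`, `timeout`, `correct`, ordered by participant, block, trial.
#' @param config A `trim_config`.
#' @return `trials` with columns `removed_reason` (one of `block_start`,
#'   `timeout`, `fast_guess`, `slow_response`, `post_timeout`,
#'   `post_fast_guess`, `post_slow`, `post_error`, `error_rt_only`, `none`),
#'   `eligible_as_target` (usable as trial N for accuracy/MPT analyses) and
#'   `eligible_rt_target` (usable as trial N for RT analyses).
#' @export
trim_trials <- function(trials, config = trim_config()) {
  if (!inherits(config, "trim_config")) stop("`config` must be trim_config()")
  need <- c("participant", "block", "trial", "rt_ms", "timeout", "correct")
  if (!all(need %in% names(trials)))
    stop("`trials` must have columns ", paste(need, collapse = ", "))
  o <- order(trials$participant, trials$block, trials$trial)
  if (!identical(o, seq_len(nrow(trials))))
    stop("`trials` must be ordered by participant, block, trial")
  to <- trials$timeout %in% TRUE
  err <- trials$correct %in% FALSE & !to
  fast <- !to & !is.na(trials$rt_ms) & trials$rt_ms < config$fast_guess_ms
  slow <- if (is.null(config$slow_cutoff_ms)) rep(FALSE, nrow(trials))
          else !to & !is.na(trials$rt_ms) & trials$rt_ms > config$slow_cutoff_ms

  reason <- rep("none", nrow(trials))
  # assign from lowest to highest precedence so later rules overwrite
  reason[err] <- "error_rt_only"
  reason[window_after(trials, err, config$post_error_window)] <- "post_error"
  reason[window_after(trials, slow, config$slow_window)] <- "post_slow"
  reason[window_after(trials, fast, config$fast_guess_window)] <- "post_fast_guess"
  reason[window_after(trials, to, config$timeout_window)] <- "post_timeout"
  reason[slow] <- "slow_response"
  reason[fast] <- "fast_guess"
  reason[to] <- "timeout"
  reason[trials$trial <= 2L] <- "block_start"

  trials$removed_reason <- reason
  trials$eligible_as_target <- reason %in% c("none", "error_rt_only")
  trials$eligible_rt_target <- reason == "none"
  trials
}

#' Participant-level exclusion
#'
#' Applies the three exclusion rules: fast-guess rate above
#' `max_fast_guess_rate` of all (raw) trials, error rate above
#' `max_error_rate`, or — when sequence labels are supplied — fewer than
#' `min_trials_per_cell` eligible targets in any cell of the analyzed
#' design. Rates are computed on the untrimmed trial counts. Cells are the
#' complete crossing of `cell_factors` with the two task-sequence levels; a
#' combination absent from the data counts as zero.
#'
#' @param trimmed Output of [trim_trials()].
#' @param config A `trim_config`.
#' @param labels Optional sequence-label table from [label_sequences()] /
#'   [median_split()], used for the cell-count rule.
#' @param cell_factors Character vector of label columns defining the
#'   analysis cells (default `c("n2_category", "n1_speed")`; `seq_type`
#'   is always crossed in).
#' @param cell_levels Optional named list restricting the levels checked for
#'   a factor (e.g. drop an N-2 error type not analyzed, as in the
#'   simplified designs).
#' @return Data frame: `participant`, `kept`, `exclusion_reason`
#'   (`fast_guess_rate`, `error_rate`, `cell_count`, or `none`).
#' @export
exclude_participants <- function(trimmed, config = trim_config(),
                                 labels = NULL,
                                 cell_factors = c("n2_category", "n1_speed"),
                                 cell_levels = NULL) {
  ids <- sort(unique(trimmed$participant))
  out <- data.frame(participant = ids, kept = TRUE,
                    exclusion_reason = "none", stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    d <- trimmed[trimmed$participant == ids[i], ]
    n <- nrow(d)
    fast_rate <- sum(!d$timeout %in% TRUE & !is.na(d$rt_ms) &
                     d$rt_ms < config$fast_guess_ms) / n
    err_rate <- sum(d$correct %in% FALSE & !d$timeout %in% TRUE) / n
    if (fast_rate > config$max_fast_guess_rate) {
      out$kept[i] <- FALSE; out$exclusion_reason[i] <- "fast_guess_rate"
    } else if (err_rate > config$max_error_rate) {
      out$kept[i] <- FALSE; out$exclusion_reason[i] <- "error_rate"
    } else if (!is.null(labels)) {
      lab <- labels[labels$participant == ids[i], , drop = FALSE]
      facs <- c("seq_type", cell_factors)
      lev <- lapply(facs, function(f) {
        if (!is.null(cell_levels[[f]])) cell_levels[[f]]
        else sort(unique(labels[[f]]))
      })
      cells <- do.call(expand.grid,
                       c(stats::setNames(lev, facs),
                         stringsAsFactors = FALSE))
      keep_lab <- rep(TRUE, nrow(lab))
      for (f in facs) if (!is.null(cell_levels[[f]]))
        keep_lab <- keep_lab & lab[[f]] %in% cell_levels[[f]]
      lab <- lab[keep_lab, , drop = FALSE]
      counts <- vapply(seq_len(nrow(cells)), function(j) {
        m <- rep(TRUE, nrow(lab))
        for (f in facs) m <- m & lab[[f]] == cells[[f]][j]
        sum(m)
      }, numeric(1))
      if (any(counts < config$min_trials_per_cell)) {
        out$kept[i] <- FALSE; out$exclusion_reason[i] <- "cell_count"
      }
    }
  }
  out
}
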