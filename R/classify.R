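#' Classify a pressed key into a response category
#'
#' Pure, vectorized mapping from (paradigm, cued task, stimulus, pressed key)
#' to the observable response category of the paradigm's classification
#' scheme:
#'
#' * univalent: correct key -> `correct`; the cued task's other key ->
#'   `response_confusion`; a wrong task's correct key for this stimulus ->
#'   `task_confusion`; the remaining keys -> `mixed`.
#' * bivalent_congruency: correct key -> `correct`; any error on a congruent
#'   trial -> `response_confusion`; any error on an incongruent trial ->
#'   `task_confusion`.
#' * three_key: correct key -> `correct`; the distractor's key ->
#'   `task_confusion`; the third key -> `response_confusion`.
#'
#' @param paradigm A `paradigm_spec`.
#' @param task,stim_id,key Parallel vectors: cued task, stimulus identity,
#'   pressed key. `NA` keys (timeouts) yield category `timeout`.
#' @return Character vector of categories in
#'   `c("correct","task_confusion","response_confusion","mixed","timeout")`.
#' @export
classify_key <- function(paradigm, task, stim_id, key) {
  stopifnot_paradigm(paradigm)
  n <- length(key)
  out <- rep(NA_character_, n)
  is_to <- is.na(key)
  out[is_to] <- "timeout"
  if (all(is_to)) return(out)
  if (!all(key[!is_to] %in% paradigm$keys))
    stop("pressed key not among the paradigm's keys")
  ck <- correct_key(paradigm, task, stim_id)
  hit <- !is_to & key == ck
  out[hit] <- "correct"
  err <- !is_to & !hit
  if (any(err)) {
    out[err] <- switch(
      paradigm$paradigm_id,
      univalent = {
        t_e <- task[err]; s_e <- stim_id[err]; k_e <- key[err]
        # wrong key of the cued task -> response confusion
        own_keys <- do.call(rbind, paradigm$task_keys[t_e])
        is_rc <- k_e == own_keys[, 1] | k_e == own_keys[, 2]
        # correct key of one of the two wrong tasks -> task confusion
        other <- lapply(t_e, function(t) setdiff(paradigm$tasks, t))
        tc1 <- correct_key(paradigm, vapply(other, `[`, "", 1L), s_e)
        tc2 <- correct_key(paradigm, vapply(other, `[`, "", 2L), s_e)
        is_tc <- k_e == tc1 | k_e == tc2
        ifelse(is_rc, "response_confusion",
               ifelse(is_tc, "task_confusion", "mixed"))
      },
      bivalent_congruency = {
        cong <- paradigm$stimuli$congruent[
          match(stim_id[err], paradigm$stimuli$stim_id)]
        ifelse(cong, "response_confusion", "task_confusion")
      },
      three_key = {
        dk <- distractor_of(paradigm, task[err], stim_id[err])$key
        ifelse(key[err] == dk, "task_confusion", "response_confusion")
      })
  }
  out
}

#' Classify all trials of a table
#'
#' Adds a `category` column (see [classify_key()]) to a trial table holding
#' `task`, `stim_id` and `pressed_key` columns. Trials with `timeout = TRUE`
#' or a missing key are categorized as `timeout`.
#'
#' @param trials Trial table.
#' @param paradigm A `paradigm_spec`.
#' @return `trials` with a `category` column.
#' @export
classify_trials <- function(trials, paradigm) {
  need <- c("task", "stim_id", "pressed_key")
  if (!all(need %in% names(trials)))
    stop("`trials` must have columns ", paste(need, collapse = ", "))
  key <- trials$pressed_key
  if ("timeout" %in% names(trials)) key[which(trials$timeout)] <- NA_character_
  trials$category <- classify_key(paradigm, trials$task, trials$stim_id, key)
  trials
}

#' Tabulate response-category counts per participant
#'
#' Counts classified trials per participant, excluding timeouts (counted
#' separately in `n_timeout`). For the congruency paradigm the counts are
#' returned in the observable space the MPT model is fitted on —
#' correct/error within each congruency stratum — since task- vs
#' response-confusion labels are aliases for congruency there.
#'
#' @param trials Classified trial table (see [classify_trials()]); only rows
#'   that should enter the counts (e.g. trimmed) are tabulated.
#' @param paradigm A `paradigm_spec`.
#' @return A data frame, one row per participant, with one column per
#'   category, plus `n_trials` (non-timeout) and `n_timeout`.
#' @export
tabulate_categories <- function(trials, paradigm) {
  stopifnot_paradigm(paradigm)
  if (!"category" %in% names(trials))
    stop("`trials` must be classified first (classify_trials)")
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  split_by <- split(trials, trials$participant)
  cats <- if (paradigm$paradigm_id == "bivalent_congruency") {
    c("correct_congruent", "error_congruent",
      "correct_incongruent", "error_incongruent")
  } else if (paradigm$paradigm_id == "univalent") {
    c("correct", "response_confusion", "task_confusion", "mixed")
  } else {
    c("correct", "task_confusion", "response_confusion")
  }
  rows <- lapply(split_by, function(d) {
    to <- d$category == "timeout"
    d <- d[!to, , drop = FALSE]
    lab <- if (paradigm$paradigm_id == "bivalent_congruency") {
      paste0(ifelse(d$category == "correct", "correct", "error"),
             ifelse(d$congruent, "_congruent", "_incongruent"))
    } else d$category
    cnt <- vapply(cats, function(cc) sum(lab == cc), numeric(1))
    c(cnt, n_trials = nrow(d), n_timeout = sum(to))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(participant = as.integer(names(split_by)), out)
  rownames(out) <- NULL
  out
}
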