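#' Construct a paradigm specification
#'
#' Builds the full description of one of the three task-switching
#' methodologies used to separate task-confusion from response-confusion
#' errors:
#'
#' * `"univalent"` — three tasks (shape, color, orientation), each stimulus
#'   dimension varies on two levels, and each task owns a disjoint pair of
#'   response keys (6 keys in total). For every stimulus, one key is correct,
#'   one is the wrong key of the cued task (response-confusion), two are the
#'   correct keys of the other tasks (task-confusion), and the remaining two
#'   are mixed errors.
#' * `"bivalent_congruency"` — three tasks, three levels per dimension, and
#'   three keys shared by all tasks. Congruent stimuli map all three
#'   dimensions to the same key; incongruent stimuli map each dimension to a
#'   different key. Errors on congruent trials are classified as
#'   response-confusion errors, errors on incongruent trials as
#'   task-confusion errors.
#' * `"three_key"` — target/distractor pairs drawn from three ordered
#'   categories (numbers, letters, symbols), three keys arranged by ordinal
#'   position. The distractor's key marks a task-confusion error; the third
#'   key marks a response-confusion error.
#'
#' @param paradigm_id One of `"univalent"`, `"bivalent_congruency"`,
#'   `"three_key"`.
#' @return An object of class `paradigm_spec`: a list with elements
#'   `paradigm_id`, `tasks`, `levels_per_dimension`, `keys`, `stimuli`
#'   (a data frame of the full stimulus inventory), `congruency_defined`,
#'   and (univalent only) `task_keys`.
#' @examples
#' p <- make_paradigm("three_key")
#' nrow(p$stimuli)  # 36 stimuli
#' @export
make_paradigm <- function(paradigm_id) {
  paradigm_id <- match.arg(paradigm_id,
                           c("univalent", "bivalent_congruency", "three_key"))
  spec <- switch(
    paradigm_id,
    univalent = {
      tasks <- c("shape", "color", "orientation")
      keys <- paste0("k", 1:6)
      # all 2^3 level combinations
      g <- expand.grid(lev_shape = 1:2, lev_color = 1:2, lev_orientation = 1:2)
      stimuli <- data.frame(stim_id = sprintf("u%02d", seq_len(nrow(g))), g,
                            congruent = NA, stringsAsFactors = FALSE)
      list(paradigm_id = paradigm_id, tasks = tasks,
           levels_per_dimension = 2L, keys = keys, stimuli = stimuli,
           congruency_defined = FALSE,
           task_keys = list(shape = keys[1:2], color = keys[3:4],
                            orientation = keys[5:6]))
    },
    bivalent_congruency = {
      tasks <- c("shape", "color", "orientation")
      keys <- paste0("k", 1:3)
      # 3 congruent stimuli (all dimensions point at the same key) and
      # 3 incongruent ones (cyclic level assignments, all keys distinct)
      lev <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3),
                   c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
      stimuli <- data.frame(stim_id = sprintf("b%02d", 1:6),
                            lev_shape = lev[, 1], lev_color = lev[, 2],
                            lev_orientation = lev[, 3],
                            congruent = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                            stringsAsFactors = FALSE)
      list(paradigm_id = paradigm_id, tasks = tasks,
           levels_per_dimension = 3L, keys = keys, stimuli = stimuli,
           congruency_defined = TRUE)
    },
    three_key = {
      tasks <- c("number", "letter", "symbol")
      keys <- paste0("k", 1:3)
      # 3 category pairs x 6 incongruent level assignments x 2 sides
      pairs <- utils::combn(tasks, 2)
      rows <- list()
      for (j in seq_len(ncol(pairs))) {
        for (l1 in 1:3) for (l2 in 1:3) {
          if (l1 == l2) next  # incongruent only: keys must differ
          for (side in c("LR", "RL")) {
            rows[[length(rows) + 1L]] <-
              data.frame(cat_a = pairs[1, j], lev_a = l1,
                         cat_b = pairs[2, j], lev_b = l2,
                         side = side, stringsAsFactors = FALSE)
          }
        }
      }
      stimuli <- do.call(rbind, rows)
      stimuli <- data.frame(stim_id = sprintf("t%02d", seq_len(nrow(stimuli))),
                            stimuli, congruent = FALSE,
                            stringsAsFactors = FALSE)
      list(paradigm_id = paradigm_id, tasks = tasks,
           levels_per_dimension = 3L, keys = keys, stimuli = stimuli,
           congruency_defined = FALSE)
    })
  structure(spec, class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat("<paradigm_spec>", x$paradigm_id, "\n")
  cat("  tasks:", paste(x$tasks, collapse = ", "), "\n")
  cat("  keys :", paste(x$keys, collapse = ", "),
      sprintf(" (%d stimuli)\n", nrow(x$stimuli)))
  invisible(x)
}

stopifnot_paradigm <- function(paradigm) {
  if (!inherits(paradigm, "paradigm_spec"))
    stop("`paradigm` must be a paradigm_spec built by make_paradigm()")
}

#' Correct response key for (task, stimulus)
#'
#' Vectorized lookup of the single correct key for each cued task and
#' stimulus identity.
#'
#' @param paradigm A `paradigm_spec`.
#' @param task Character vector of cued tasks.
#' @param stim_id Character vector of stimulus identities (same length).
#' @return Character vector of key labels.
#' @export
correct_key <- function(paradigm, task, stim_id) {
  stopifnot_paradigm(paradigm)
  st <- paradigm$stimuli[match(stim_id, paradigm$stimuli$stim_id), , drop = FALSE]
  if (anyNA(st$stim_id)) stop("unknown stim_id")
  if (!all(task %in% paradigm$tasks)) stop("unknown task label")
  if (paradigm$paradigm_id == "three_key") {
    lev <- ifelse(task == st$cat_a, st$lev_a,
                  ifelse(task == st$cat_b, st$lev_b, NA_integer_))
    if (anyNA(lev)) stop("cued task not afforded by stimulus")
    paradigm$keys[lev]
  } else {
    lev <- st[cbind(seq_len(nrow(st)), match(paste0("lev_", task), names(st)))]
    lev <- as.integer(lev)
    if (paradigm$paradigm_id == "univalent") {
      mapply(function(t, l) paradigm$task_keys[[t]][l], task, lev,
             USE.NAMES = FALSE)
    } else {
      paradigm$keys[lev]
    }
  }
}

#' Distractor task and key (three-key paradigm)
#'
#' For the three-key design, each stimulus pairs a target element (the cued
#' category) with a distractor element of another category. Returns the
#' distractor's category and its mapped key.
#'
#' @inheritParams correct_key
#' @return A data frame with columns `task` and `key`.
#' @export
distractor_of <- function(paradigm, task, stim_id) {
  stopifnot_paradigm(paradigm)
  if (paradigm$paradigm_id != "three_key")
    stop("distractor_of() is defined only for the three_key paradigm")
  st <- paradigm$stimuli[match(stim_id, paradigm$stimuli$stim_id), , drop = FALSE]
  a_is_target <- task == st$cat_a
  b_is_target <- task == st$cat_b
  if (!all(a_is_target | b_is_target)) stop("cued task not afforded by stimulus")
  data.frame(task = ifelse(a_is_target, st$cat_b, st$cat_a),
             key = paradigm$keys[ifelse(a_is_target, st$lev_b, st$lev_a)],
             stringsAsFactors = FALSE)
}

#' Response keys afforded by a task
#'
#' The set of keys a participant executing `task` chooses among: the task's
#' own key pair under the univalent mapping, all three shared keys otherwise.
#'
#' @inheritParams correct_key
#' @param task A single task label.
#' @return Character vector of key labels.
#' @export
afforded_keys <- function(paradigm, task) {
  stopifnot_paradigm(paradigm)
  if (paradigm$paradigm_id == "univalent") paradigm$task_keys[[task]]
  else paradigm$keys
}

#' Enumerate the key-to-category map
#'
#' For every (cued task, stimulus, key) triple of the paradigm, the response
#' category that pressing that key would produce. This is the exhaustive
#' classification table implied by the paradigm's scheme; it underlies both
#' classification and the structural invariants (exactly one correct key per
#' (task, stimulus); role counts per stimulus: univalent 1 correct / 1 RC /
#' 2 TC / 2 mixed, three-key and bivalent 1 correct / 2 error keys).
#'
#' @param paradigm A `paradigm_spec`.
#' @return A data frame with columns `task`, `stim_id`, `key`, `category`.
#' @export
key_roles <- function(paradigm) {
  stopifnot_paradigm(paradigm)
  st <- paradigm$stimuli
  if (paradigm$paradigm_id == "three_key") {
    afford <- function(s) c(s$cat_a, s$cat_b)
    grid <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
      expand.grid(task = afford(st[i, ]), stim_id = st$stim_id[i],
                  key = paradigm$keys, stringsAsFactors = FALSE)
    }))
  } else {
    grid <- expand.grid(task = paradigm$tasks, stim_id = st$stim_id,
                        key = paradigm$keys, stringsAsFactors = FALSE)
  }
  grid$category <- classify_key(paradigm, grid$task, grid$stim_id, grid$key)
  grid[order(grid$task, grid$stim_id, grid$key), ]
}
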