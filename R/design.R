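#' Generate a switch-only task sequence with exact triplet balance
#'
#' Produces the cued-task sequence of a task-switching session in which the
#' task switches on every trial and, within each block, the number of N-2
#' repetition triplets (ABA: the task of trial N returns to that of trial
#' N-2) equals the number of N-2 switch triplets (CBA: all three tasks
#' differ).
#'
#' With three tasks and no immediate repetitions, every trial from the third
#' onwards makes a binary move: return to the task of two trials back (an ABA
#' triplet) or go to the third task (a CBA triplet). The sequence is built by
#' shuffling an exactly balanced vector of these moves, so triplet balance is
#' exact by construction and no rejection sampling is needed.
#'
#' @param n_blocks Number of blocks.
#' @param block_length Trials per block; `block_length - 2` must be even and
#'   positive so the ABA/CBA counts can be equal.
#' @param seed Optional integer seed (reproducible output).
#' @param tasks Character vector of exactly 3 task labels.
#' @return A data frame with columns `block`, `trial` (within block), `task`.
#' @examples
#' s <- generate_task_sequence(2, 24, seed = 1)
#' all(s$task[-1] != s$task[-nrow(s)])
#' @export
generate_task_sequence <- function(n_blocks, block_length, seed = NULL,
                                   tasks = c("shape", "color", "orientation")) {
  if (length(tasks) != 3L || anyDuplicated(tasks))
    stop("`tasks` must be 3 distinct labels")
  n_blocks <- as.integer(n_blocks); block_length <- as.integer(block_length)
  if (n_blocks < 1L) stop("`n_blocks` must be >= 1")
  n_triplets <- block_length - 2L
  if (block_length < 4L || n_triplets %% 2L != 0L)
    stop("`block_length` must be >= 4 with an even number of triplets ",
         "(block_length - 2) so that ABA and CBA counts can be equal")
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      aba <- sample(rep(c(TRUE, FALSE), each = n_triplets %/% 2L))
      ti <- integer(block_length)
      ti[1:2] <- sample.int(3L, 2L)
      for (i in 3:block_length) {
        # with 3 tasks and no immediate repeats, the non-ABA move is
        # forced: indices of the three tasks sum to 6
        ti[i] <- if (aba[i - 2L]) ti[i - 2L] else 6L - ti[i - 1L] - ti[i - 2L]
      }
      data.frame(block = b, trial = seq_len(block_length), task = tasks[ti],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
}

#' Count ABA and CBA triplets
#'
#' Tabulates triplet types of a task sequence: for each trial from the third
#' onward within a block, ABA if its task equals that of two trials back,
#' CBA otherwise.
#'
#' @param task Character vector of tasks (one block).
#' @return Named integer vector `c(aba = ..., cba = ...)`.
#' @export
count_triplets <- function(task) {
  n <- length(task)
  if (n < 3L) return(c(aba = 0L, cba = 0L))
  idx <- 3:n
  aba <- sum(task[idx] == task[idx - 2L])
  c(aba = aba, cba = length(idx) - aba)
}

#' Assign stimuli to a task sequence
#'
#' Draws a stimulus identity for every trial, uniformly from the paradigm's
#' inventory restricted to stimuli that afford the cued task, under the
#' constraint that a stimulus shown on trial N never reappears on trials
#' N+1 or N+2 (so N-2 repetition costs cannot be confounded with episodic
#' stimulus repetition). The lag constraint is enforced across block
#' boundaries as well.
#'
#' Assignment is vectorized: an unconstrained draw is followed by redraws of
#' the violating positions until no lag-1/lag-2 repeats remain (each redraw
#' pass is vectorized; convergence is geometric for the inventories used
#' here). A sequential fallback guards pathological cases.
#'
#' @param task_sequence Data frame from [generate_task_sequence()].
#' @param paradigm A `paradigm_spec`.
#' @param seed Optional integer seed.
#' @param csi_ms Cue-stimulus interval stored per trial (ms). Plays no
#'   computational role; kept to represent preparation-time groups.
#' @return The design table: `block`, `trial`, `task`, `stim_id`,
#'   `congruent`, `csi_ms`.
#' @export
assign_stimuli <- function(task_sequence, paradigm, seed = NULL, csi_ms = 400) {
  stopifnot_paradigm(paradigm)
  if (!all(c("block", "trial", "task") %in% names(task_sequence)))
    stop("`task_sequence` must have columns block, trial, task")
  if (!all(task_sequence$task %in% paradigm$tasks))
    stop("task labels do not match the paradigm")
  st <- paradigm$stimuli
  inventory <- lapply(paradigm$tasks, function(t) {
    if (paradigm$paradigm_id == "three_key")
      st$stim_id[st$cat_a == t | st$cat_b == t]
    else st$stim_id
  })
  names(inventory) <- paradigm$tasks
  if (min(lengths(inventory)) < 3L)
    stop("stimulus inventory too small for the lag-2 constraint")
  n <- nrow(task_sequence)
  with_seed(seed, {
    pool_idx <- match(task_sequence$task, paradigm$tasks)
    draw <- function(i) {
      out <- character(length(i))
      for (t in seq_along(inventory)) {
        sel <- which(pool_idx[i] == t)
        if (length(sel)) {
          pool <- inventory[[t]]
          out[sel] <- pool[sample.int(length(pool), length(sel),
                                      replace = TRUE)]
        }
      }
      out
    }
    stim <- draw(seq_len(n))
    for (pass in 1:100) {
      lag1 <- c(FALSE, stim[-1] == stim[-n])
      lag2 <- c(FALSE, FALSE, stim[-(1:2)] == stim[seq_len(n - 2L)])
      bad <- which(lag1 | lag2)
      if (!length(bad)) break
      stim[bad] <- draw(bad)
    }
    # sequential fallback (rarely, if ever, reached)
    if (n > 1L) for (i in 2:n) {
      ctx <- stim[max(1L, i - 2L):(i - 1L)]
      if (stim[i] %in% ctx) {
        ok <- setdiff(inventory[[pool_idx[i]]], ctx)
        if (!length(ok)) stop("stimulus assignment infeasible at trial ", i)
        stim[i] <- sample_one(ok)
      }
    }
    out <- task_sequence
    out$stim_id <- stim
    out$congruent <- if (paradigm$congruency_defined)
      st$congruent[match(stim, st$stim_id)] else NA
    out$csi_ms <- csi_ms
    out
  })
}

#' Build a multi-participant design
#'
#' Convenience wrapper generating one lawful task/stimulus design per
#' participant (each from a seed derived deterministically from `seed`).
#'
#' @inheritParams assign_stimuli
#' @param paradigm A `paradigm_spec`.
#' @param n_participants Number of participants.
#' @param n_blocks,block_length Passed to [generate_task_sequence()].
#' @param seed Optional integer master seed.
#' @return Design table with a leading `participant` column.
#' @export
make_design <- function(paradigm, n_participants, n_blocks, block_length,
                        seed = NULL, csi_ms = 400) {
  stopifnot_paradigm(paradigm)
  out <- lapply(seq_len(n_participants), function(p) {
    ts <- generate_task_sequence(n_blocks, block_length,
                                 seed = child_seed(seed, 2L * p),
                                 tasks = paradigm$tasks)
    d <- assign_stimuli(ts, paradigm, seed = child_seed(seed, 2L * p + 1L),
                        csi_ms = csi_ms)
    cbind(participant = p, d)
  })
  do.call(rbind, out)
}

#' Write / read a design table as CSV
#'
#' @param design Design table (as from [make_design()]).
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_trials_csv`
#'   returns a data frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
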