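#' Latent-process parameters for the trial simulator
#'
#' Bundles the parameters of the generative model: on each trial the cued
#' task is selected with probability `T`; given the selected task, its
#' correct response is chosen with probability `R`; when both selection and
#' response fail, the remaining two-way choice is random with probability
#' `RE` (fixed at 0.5, the random-execution assumption of the MPT models).
#' Reaction times are shifted-lognormal with post-error slowing, an
#' injectable N-2 repetition cost `delta_n2`, and a slow error-correction
#' mechanism: after an N-2 task-selection failure the cost is restored only
#' if a correction process fired on the (typically slowed) N-1 trial, with
#' probability `plogis(kappa * (rt_n1 - tau))`.
#'
#' @param T Probability of correct task selection, in \[0, 1\].
#' @param R Probability of correct response selection for the selected task.
#' @param RE Random-execution probability for the final two-way split
#'   (default 0.5; override only for sensitivity analysis).
#' @param rt_mu,rt_sigma Location and scale of the log-RT baseline
#'   (defaults `log(550)` and 0.25, i.e. a ~550 ms median).
#' @param delta_n2 N-2 repetition cost injected when inhibition applies (ms).
#' @param pes Post-error slowing added after an observed error (ms).
#' @param tau Threshold of the correction probability on the N-1 RT (ms);
#'   default `exp(rt_mu)`, the baseline median. `-Inf`/`Inf` give the
#'   always/never regimes used in tests.
#' @param kappa Slope of the correction probability (1/ms).
#' @param timeout_ms Response deadline; responses slower than this are
#'   recorded as timeouts with no key. `NULL` disables the deadline
#'   (the no-response-limit group).
#' @return An object of class `latent_params`.
#' @export
latent_params <- function(T = 0.9, R = 0.9, RE = 0.5,
                          rt_mu = log(550), rt_sigma = 0.25,
                          delta_n2 = 30, pes = 60,
                          tau = NULL, kappa = 0.01,
                          timeout_ms = 2000) {
  p <- list(T = T, R = R, RE = RE, rt_mu = rt_mu, rt_sigma = rt_sigma,
            delta_n2 = delta_n2, pes = pes,
            tau = if (is.null(tau)) exp(rt_mu) else tau,
            kappa = kappa, timeout_ms = timeout_ms)
  for (nm in c("T", "R", "RE")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a probability in [0, 1]")
  }
  if (!is.numeric(p$rt_sigma) || p$rt_sigma <= 0) stop("`rt_sigma` must be > 0")
  if (!is.null(p$timeout_ms) && p$timeout_ms <= 0)
    stop("`timeout_ms` must be positive or NULL")
  structure(p, class = "latent_params")
}

#' Simulate key presses from the latent selection process
#'
#' For every design trial, draws the latent task selection (cued task with
#' probability `T`; otherwise the distractor's task under the three-key
#' paradigm, or one of the two irrelevant tasks uniformly under the other
#' paradigms), then the response: the selected task's correct key with
#' probability `R`, otherwise one of the remaining keys of the selected
#' task's afforded set, with the cued-correct key (when among them) taken
#' with probability `RE`.
#'
#' @param design Design table (from [make_design()] or [assign_stimuli()]).
#' @param paradigm A `paradigm_spec`.
#' @param latent A `latent_params` object.
#' @param seed Optional integer seed.
#' @return `design` plus columns `latent_selected_task`,
#'   `latent_response_correct`, `pressed_key`, `correct`.
#' @export
simulate_responses <- function(design, paradigm, latent, seed = NULL) {
  stopifnot_paradigm(paradigm)
  if (!inherits(latent, "latent_params")) stop("`latent` must be latent_params()")
  n <- nrow(design)
  with_seed(seed, {
    sel_ok <- stats::runif(n) < latent$T
    sel_task <- design$task
    if (any(!sel_ok)) {
      if (paradigm$paradigm_id == "three_key") {
        sel_task[!sel_ok] <- distractor_of(paradigm, design$task[!sel_ok],
                                           design$stim_id[!sel_ok])$task
      } else {
        w <- which(!sel_ok)
        others <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))  # non-cued tasks
        ci <- match(design$task[w], paradigm$tasks)
        pick <- 1L + (stats::runif(length(w)) < 0.5)
        sel_task[w] <- paradigm$tasks[others[cbind(ci, pick)]]
      }
    }
    resp_ok <- stats::runif(n) < latent$R
    sel_ck <- correct_key(paradigm, sel_task, design$stim_id)
    cued_ck <- correct_key(paradigm, design$task, design$stim_id)
    pressed <- sel_ck
    miss <- which(!resp_ok)
    if (length(miss)) {
      if (paradigm$paradigm_id == "univalent") {
        # the selected task owns exactly two keys: take the other one
        tk <- do.call(rbind, paradigm$task_keys[sel_task[miss]])
        pressed[miss] <- ifelse(sel_ck[miss] == tk[, 1], tk[, 2], tk[, 1])
      } else {
        # two remaining shared keys; the cued-correct one (if among them)
        # is hit with probability RE, else the split is uniform
        u <- stats::runif(length(miss))
        k <- paradigm$keys
        others <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))  # non-correct keys
        cki <- match(sel_ck[miss], k)
        rem1 <- k[others[cki, 1]]
        rem2 <- k[others[cki, 2]]
        cued_in <- cued_ck[miss] == rem1 | cued_ck[miss] == rem2
        other_rem <- ifelse(cued_ck[miss] == rem1, rem2, rem1)
        pressed[miss] <- ifelse(
          cued_in,
          ifelse(u < latent$RE, cued_ck[miss], other_rem),
          ifelse(u < 0.5, rem1, rem2))
      }
    }
    out <- design
    out$latent_selected_task <- sel_task
    out$latent_response_correct <- resp_ok
    out$pressed_key <- pressed
    out$correct <- pressed == cued_ck
    out
  })
}

#' Simulate reaction times with N-2 inhibition and slow error correction
#'
#' Fills `rt_ms` for a response-simulated trial table. The RT of trial N is
#' `exp(Normal(rt_mu, rt_sigma)) + pes * [trial N-1 was an observed error]
#' + delta_n2 * [inhibition applies]`, truncated at `timeout_ms` when a
#' deadline is set (timeouts lose their key).
#'
#' Inhibition applies on trial N when the cued task of N equals the cued
#' task of N-2 (an ABA triplet) and either task selection at N-2 succeeded,
#' or the error-correction process fired on trial N-1. The correction fires
#' with probability `plogis(kappa * (rt(N-1) - tau))`, i.e. mostly on slow
#' post-error trials — the mechanism that restores N-2 repetition costs
#' after slow N-1 responses. Blocks are independent: no carry-over of
#' post-error slowing, inhibition, or correction across block boundaries.
#'
#' @param trials Trial table from [simulate_responses()], ordered by
#'   participant, block, trial.
#' @param latent A `latent_params` object.
#' @param seed Optional integer seed.
#' @return `trials` plus `rt_ms`, `timeout`, `latent_correction` (the
#'   correction indicator attached to the trial it fired on) and
#'   `latent_inhibition`.
#' @export
simulate_rts <- function(trials, latent, seed = NULL) {
  if (!inherits(latent, "latent_params")) stop("`latent` must be latent_params()")
  need <- c("block", "trial", "task", "latent_selected_task", "correct")
  if (!all(need %in% names(trials)))
    stop("`trials` must come from simulate_responses()")
  if (!"participant" %in% names(trials)) trials$participant <- 1L
  n <- nrow(trials)
  grp <- cumsum(c(TRUE, trials$participant[-1] != trials$participant[-n] |
                        trials$block[-1] != trials$block[-n]))
  pos <- stats::ave(seq_len(n), grp, FUN = seq_along)
  with_seed(seed, {
    base <- exp(stats::rnorm(n, latent$rt_mu, latent$rt_sigma))
    u_corr <- stats::runif(n)
    sel_ok <- trials$latent_selected_task == trials$task
    rt <- numeric(n)
    correction <- logical(n)
    inhib <- logical(n)
    maxp <- max(pos)
    idx_by_pos <- split(seq_len(n), pos)
    for (p in seq_len(maxp)) {
      i <- idx_by_pos[[as.character(p)]]
      prev_err <- rep(FALSE, length(i))
      if (p >= 2L) {
        i1 <- i - 1L  # same group: rows are contiguous within a block
        # correction fires on trial N-1 as a function of its (latent) RT
        x <- latent$kappa * (rt[i1] - latent$tau)
        pcorr <- stats::plogis(x)
        pcorr[is.nan(pcorr)] <- 0.5  # kappa = 0 and tau = +/-Inf edge
        correction[i1] <- u_corr[i1] < pcorr
        # post-error slowing: observed (non-timeout) error on N-1
        prev_err <- !trials$correct[i1]
        if (!is.null(latent$timeout_ms))
          prev_err <- prev_err & rt[i1] <= latent$timeout_ms
      }
      if (p >= 3L) {
        i2 <- i - 2L
        inhib[i] <- trials$task[i] == trials$task[i2] &
          (sel_ok[i2] | correction[i - 1L])
      }
      rt[i] <- base[i] + latent$pes * prev_err + latent$delta_n2 * inhib[i]
    }
    out <- trials
    out$rt_ms <- rt
    out$timeout <- FALSE
    if (!is.null(latent$timeout_ms)) {
      to <- rt > latent$timeout_ms
      out$timeout <- to
      out$rt_ms[to] <- NA_real_
      out$pressed_key[to] <- NA_character_
      out$correct[to] <- NA
    }
    out$latent_correction <- correction
    out$latent_inhibition <- inhib
    out
  })
}

#' Simulate a full synthetic experiment
#'
#' Design generation, response simulation, RT simulation and classification
#' in one call, with per-stage seeds derived from `seed`.
#'
#' @param paradigm A `paradigm_spec`.
#' @param n_participants,n_blocks,block_length Design dimensions.
#' @param latent A `latent_params` object.
#' @param seed Integer master seed.
#' @param csi_ms Cue-stimulus interval (ms).
#' @return A classified trial table (see [classify_trials()]).
#' @export
simulate_experiment <- function(paradigm, n_participants, n_blocks,
                                block_length, latent, seed = NULL,
                                csi_ms = 400) {
  design <- make_design(paradigm, n_participants, n_blocks, block_length,
                        seed = child_seed(seed, 1L), csi_ms = csi_ms)
  trials <- simulate_responses(design, paradigm, latent,
                               seed = child_seed(seed, 2L))
  trials <- simulate_rts(trials, latent, seed = child_seed(seed, 3L))
  classify_trials(trials, paradigm)
}
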