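#' Observable category probabilities of the MPT models
#'
#' Evaluates the multinomial-processing-tree equations mapping the latent
#' probabilities of correct task selection (`T`) and correct response
#' selection (`R`) to the observable response categories.
#'
#' `exp2_congruency` (bivalent stimuli, congruency classification) has two
#' trial-type strata, each a multinomial summing to 1:
#' \deqn{p(correct | congruent) = TR + (1-T)R}
#' \deqn{p(error | congruent) = T(1-R) + (1-T)(1-R)}
#' \deqn{p(correct | incongruent) = TR + (1-T)(1-R)\,RE}
#' \deqn{p(error | incongruent) = T(1-R) + (1-T)R + (1-T)(1-R)\,RE}
#'
#' `exp3_three_key` (target/distractor design) has one stratum with three
#' categories:
#' \deqn{p(correct) = TR + (1-T)(1-R)\,RE}
#' \deqn{p(TC) = T(1-R)\,RE + (1-T)R}
#' \deqn{p(RC) = T(1-R)\,RE + (1-T)(1-R)\,RE}
#' where TC/RC are task-/response-confusion errors and the random-execution
#' probability RE is fixed at 0.5. (The published equation set for this tree
#' carries a typographic slip in the `correct` line; the branch structure of
#' the tree — which these equations implement — is the version under which
#' the three probabilities sum to 1 and the conditional-probability
#' denominators are consistent.)
#'
#' @param model_id `"exp2_congruency"` or `"exp3_three_key"`.
#' @param T,R Latent probabilities in \[0, 1\] (vectorized).
#' @param RE Random-execution probability (fixed 0.5 by assumption).
#' @return A data frame with one row per (T, R) pair; columns are the
#'   category probabilities (`correct_congruent`, `error_congruent`,
#'   `correct_incongruent`, `error_incongruent` for exp2; `correct`,
#'   `task_confusion`, `response_confusion` for exp3).
#' @examples
#' category_probabilities("exp3_three_key", T = 0.9, R = 0.8)
#' @export
category_probabilities <- function(model_id, T, R, RE = 0.5) {
  model_id <- match.arg(model_id, c("exp2_congruency", "exp3_three_key"))
  if (any(T < 0 | T > 1, na.rm = TRUE) || any(R < 0 | R > 1, na.rm = TRUE) ||
      anyNA(T) || anyNA(R))
    stop("T and R must lie in [0, 1]")
  if (model_id == "exp2_congruency") {
    data.frame(
      correct_congruent   = T * R + (1 - T) * R,
      error_congruent     = T * (1 - R) + (1 - T) * (1 - R),
      correct_incongruent = T * R + (1 - T) * (1 - R) * RE,
      error_incongruent   = T * (1 - R) + (1 - T) * R + (1 - T) * (1 - R) * RE)
  } else {
    data.frame(
      correct            = T * R + (1 - T) * (1 - R) * RE,
      task_confusion     = T * (1 - R) * RE + (1 - T) * R,
      response_confusion = T * (1 - R) * RE + (1 - T) * (1 - R) * RE)
  }
}

mpt_categories <- function(model_id) {
  if (model_id == "exp2_congruency")
    c("correct_congruent", "error_congruent",
      "correct_incongruent", "error_incongruent")
  else c("correct", "task_confusion", "response_confusion")
}

# product-multinomial log-likelihood of counts at (T, R); exp2 is the
# product of the congruent and incongruent strata sharing (T, R)
mpt_loglik <- function(model_id, counts, T, R, RE = 0.5) {
  p <- as.numeric(category_probabilities(model_id, T, R, RE))
  sum(counts * log(pmax(p, 1e-300)))
}

# analytic gradient of the log-likelihood in (T, R)
mpt_loglik_grad <- function(model_id, counts, T, R, RE = 0.5) {
  p <- as.numeric(category_probabilities(model_id, T, R, RE))
  if (model_id == "exp2_congruency") {
    dT <- c(0, 0, R - (1 - R) * RE, -(R - (1 - R) * RE))
    dR <- c(1, -1, T - (1 - T) * RE, -(T - (1 - T) * RE))
  } else {
    dT <- c(R - (1 - R) * RE, (1 - R) * RE - R, 0)
    dR <- c(T - (1 - T) * RE, (1 - T) - T * RE, -RE)
  }
  w <- counts / pmax(p, 1e-300)
  c(sum(w * dT), sum(w * dR))
}

#' Fit an MPT model to one participant's category counts
#'
#' Maximizes the product-multinomial log-likelihood of the observed category
#' counts over (T, R) in the unit square, by bounded quasi-Newton
#' (`L-BFGS-B`) from five deterministic starting points; the best solution
#' wins. Both models are saturated (as many free parameters as independent
#' category proportions), so at an interior optimum the fitted
#' probabilities reproduce the observed proportions and the likelihood-ratio
#' statistic G-squared is ~0; a boundary optimum (T or R pinned at 0/1) is
#' flagged, not an error.
#'
#' @param counts Named numeric vector of category counts; names must be the
#'   model's categories (see [category_probabilities()]). For
#'   `exp2_congruency` both congruency strata must be present with
#'   nonzero totals.
#' @param model_id `"exp2_congruency"` or `"exp3_three_key"`.
#' @param RE Random-execution probability (fixed 0.5).
#' @return An object of class `mpt_fit`: list with `T_hat`, `R_hat`,
#'   `loglik`, `G2`, `df` (0 for these saturated models), `converged`,
#'   `boundary`, `model_id`.
#' @examples
#' fit_mpt(c(correct = 7300, task_confusion = 1700,
#'           response_confusion = 1000), "exp3_three_key")
#' @export
fit_mpt <- function(counts, model_id, RE = 0.5) {
  model_id <- match.arg(model_id, c("exp2_congruency", "exp3_three_key"))
  cats <- mpt_categories(model_id)
  if (is.null(names(counts)) || !all(cats %in% names(counts)))
    stop("`counts` must be named with categories: ",
         paste(cats, collapse = ", "))
  counts <- counts[cats]
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("all counts are zero; nothing to fit")
  if (model_id == "exp2_congruency" &&
      (sum(counts[1:2]) == 0 || sum(counts[3:4]) == 0))
    stop("exp2_congruency requires counts in both congruency strata")

  nll <- function(par) -mpt_loglik(model_id, counts, par[1], par[2], RE)
  ngr <- function(par) -mpt_loglik_grad(model_id, counts, par[1], par[2], RE)
  starts <- list(c(0.5, 0.5), c(0.9, 0.9), c(0.99, 0.8),
                 c(0.8, 0.99), c(0.7, 0.7))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, gr = ngr, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, 1),
                      control = list(factr = 1e2, pgtol = 1e-12,
                                     maxit = 500L))
    if (is.null(best) || o$value < best$value) best <- o
  }
  T_hat <- best$par[1]; R_hat <- best$par[2]
  # G2 = 2 * sum obs * log(obs / expected), per stratum, with 0*log(0) = 0
  p <- as.numeric(category_probabilities(model_id, T_hat, R_hat, RE))
  expected <- if (model_id == "exp2_congruency") {
    c(p[1:2] * sum(counts[1:2]), p[3:4] * sum(counts[3:4]))
  } else p * sum(counts)
  nz <- counts > 0
  G2 <- 2 * sum(counts[nz] * log(counts[nz] / pmax(expected[nz], 1e-300)))
  structure(list(
    T_hat = T_hat, R_hat = R_hat,
    loglik = -best$value, G2 = max(G2, 0), df = 0L,
    converged = best$convergence == 0L,
    boundary = min(T_hat, 1 - T_hat, R_hat, 1 - R_hat) < 1e-5,
    model_id = model_id), class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat(sprintf("<mpt_fit %s> T = %.4f, R = %.4f, logLik = %.3f, G2 = %.2e%s\n",
              x$model_id, x$T_hat, x$R_hat, x$loglik, x$G2,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Fit an MPT model per participant
#'
#' Applies [fit_mpt()] to every row of a per-participant count table (as
#' produced by [tabulate_categories()]).
#'
#' @param count_table Data frame with a `participant` column and one column
#'   per category.
#' @inheritParams fit_mpt
#' @return Data frame: participant, T_hat, R_hat, loglik, G2, converged,
#'   boundary.
#' @export
fit_mpt_all <- function(count_table, model_id, RE = 0.5) {
  cats <- mpt_categories(model_id)
  rows <- lapply(seq_len(nrow(count_table)), function(i) {
    cnt <- unlist(count_table[i, cats])
    f <- fit_mpt(cnt, model_id, RE)
    data.frame(participant = count_table$participant[i],
               T_hat = f$T_hat, R_hat = f$R_hat, loglik = f$loglik,
               G2 = f$G2, converged = f$converged, boundary = f$boundary)
  })
  do.call(rbind, rows)
}

#' Conditional probability that an observed error reflects a task-selection
#' failure
#'
#' Divides the mass of the tree branches that contain the task-selection
#' failure factor (1 - T) and end in a given error category by the total
#' mass of that category:
#'
#' * exp2: p(tsf | error incongruent) =
#'   \eqn{[(1-T)R + (1-T)(1-R)RE] / [T(1-R) + (1-T)R + (1-T)(1-R)RE]};
#'   p(tsf | error congruent) = \eqn{(1-T)(1-R) / [T(1-R) + (1-T)(1-R)]}.
#' * exp3: p(tsf | TC) = \eqn{(1-T)R / [T(1-R)RE + (1-T)R]};
#'   p(tsf | RC) = \eqn{(1-T)(1-R)RE / [T(1-R)RE + (1-T)(1-R)RE]}.
#'
#' In both models p(tsf | response-confusion error) reduces algebraically to
#' `1 - T`. A category with zero probability has an undefined conditional
#' probability, returned as `NA`.
#'
#' @inheritParams category_probabilities
#' @return Data frame with columns `p_tsf_given_TC` (errors classified as
#'   task confusions: incongruent errors under exp2) and `p_tsf_given_RC`
#'   (response confusions: congruent errors under exp2).
#' @examples
#' conditional_failure_probs("exp3_three_key", T = 0.934, R = 0.932)
#' @export
conditional_failure_probs <- function(model_id, T, R, RE = 0.5) {
  model_id <- match.arg(model_id, c("exp2_congruency", "exp3_three_key"))
  if (any(T < 0 | T > 1) || any(R < 0 | R > 1)) stop("T and R must lie in [0, 1]")
  if (model_id == "exp2_congruency") {
    num_tc <- (1 - T) * R + (1 - T) * (1 - R) * RE
    den_tc <- T * (1 - R) + (1 - T) * R + (1 - T) * (1 - R) * RE
    num_rc <- (1 - T) * (1 - R)
    den_rc <- T * (1 - R) + (1 - T) * (1 - R)
  } else {
    num_tc <- (1 - T) * R
    den_tc <- T * (1 - R) * RE + (1 - T) * R
    num_rc <- (1 - T) * (1 - R) * RE
    den_rc <- T * (1 - R) * RE + (1 - T) * (1 - R) * RE
  }
  data.frame(p_tsf_given_TC = ifelse(den_tc > 0, num_tc / den_tc, NA_real_),
             p_tsf_given_RC = ifelse(den_rc > 0, num_rc / den_rc, NA_real_))
}

#' Direct failure-probability estimators for the univalent paradigm
#'
#' Under univalent response sets each response category is uniquely linked
#' to one processing path, so no model fitting is needed: the probability of
#' a task-selection failure is estimated as (task-confusion + mixed errors)
#' divided by the number of trials, and the probability of a task-execution
#' failure as (response-confusion + mixed errors) divided by the number of
#' trials. Mixed errors are intentionally counted in both, since they arise
#' from a joint failure of both processes.
#'
#' @param counts Named numeric vector (or one-row data frame) with entries
#'   `correct`, `response_confusion`, `task_confusion`, `mixed`.
#' @return List with `p_task_selection_failure` and
#'   `p_task_execution_failure`.
#' @examples
#' exp1_failure_probs(c(correct = 900, response_confusion = 50,
#'                      task_confusion = 30, mixed = 20))
#' @export
exp1_failure_probs <- function(counts) {
  counts <- unlist(counts)
  need <- c("correct", "response_confusion", "task_confusion", "mixed")
  if (!all(need %in% names(counts)))
    stop("`counts` must contain: ", paste(need, collapse = ", "))
  counts <- counts[need]
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) stop("no trials")
  list(p_task_selection_failure =
         unname((counts["task_confusion"] + counts["mixed"]) / n),
       p_task_execution_failure =
         unname((counts["response_confusion"] + counts["mixed"]) / n))
}
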