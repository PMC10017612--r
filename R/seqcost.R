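#' Label eligible target trials with sequence context
#'
#' For every trial N that survives trimming as an RT target, records the
#' triplet type (N-2 repetition, ABA, when the cued task of N equals that of
#' N-2; N-2 switch, CBA, otherwise), the classified response category of the
#' N-2 trial, the N-1 reaction time, and — when the latent simulation labels
#' are present — the latent outcome of the N-2 trial (`correct`,
#' `task_selection_failure`, `task_execution_failure`).
#'
#' A target requires its N-1 and N-2 trials to exist within the same block,
#' and its N-1 trial to be correct with a valid RT (the trimming windows
#' already remove targets after N-1 errors, timeouts and fast guesses; the
#' conditions are re-checked defensively here).
#'
#' @param trimmed Classified, trimmed trial table ([classify_trials()] then
#'   [trim_trials()]), ordered by participant, block, trial.
#' @return Data frame: `participant`, `block`, `trial`, `task`, `rt_ms`,
#'   `seq_type`, `n2_category`, `n2_congruent` (if available), `n1_rt`,
#'   and `n2_latent` when latent columns are present.
#' @export
label_sequences <- function(trimmed) {
  need <- c("participant", "block", "trial", "task", "rt_ms", "correct",
            "category", "eligible_rt_target")
  if (!all(need %in% names(trimmed)))
    stop("`trimmed` must be classified and trimmed (missing: ",
         paste(setdiff(need, names(trimmed)), collapse = ", "), ")")
  n <- nrow(trimmed)
  same_block <- function(k) {
    ok <- rep(FALSE, n)
    idx <- seq_len(n) > k
    ok[idx] <- trimmed$participant[idx] == trimmed$participant[which(idx) - k] &
               trimmed$block[idx] == trimmed$block[which(idx) - k] &
               trimmed$trial[idx] == trimmed$trial[which(idx) - k] + k
    ok
  }
  has1 <- same_block(1L); has2 <- same_block(2L)
  i <- which(trimmed$eligible_rt_target & has1 & has2)
  i1 <- i - 1L; i2 <- i - 2L
  ok_n1 <- trimmed$correct[i1] %in% TRUE & !is.na(trimmed$rt_ms[i1])
  i <- i[ok_n1]; i1 <- i1[ok_n1]; i2 <- i2[ok_n1]
  out <- data.frame(
    participant = trimmed$participant[i],
    block = trimmed$block[i], trial = trimmed$trial[i],
    task = trimmed$task[i], rt_ms = trimmed$rt_ms[i],
    seq_type = ifelse(trimmed$task[i] == trimmed$task[i2],
                      "n2_repetition", "n2_switch"),
    n2_category = trimmed$category[i2],
    n1_rt = trimmed$rt_ms[i1],
    stringsAsFactors = FALSE)
  if ("congruent" %in% names(trimmed)) out$n2_congruent <- trimmed$congruent[i2]
  if (all(c("latent_selected_task", "latent_response_correct") %in%
          names(trimmed))) {
    sel_ok <- trimmed$latent_selected_task[i2] == trimmed$task[i2]
    out$n2_latent <- ifelse(!sel_ok, "task_selection_failure",
                            ifelse(trimmed$latent_response_correct[i2],
                                   "correct", "task_execution_failure"))
  }
  out
}

#' Median split of N-1 reaction times
#'
#' Adds the `n1_speed` factor: per participant, over all of that
#' participant's labelled targets, N-1 RTs strictly below the median are
#' `fast`, those at or above it `slow` (ties go to slow).
#'
#' @param labels Output of [label_sequences()].
#' @return `labels` plus `n1_speed`.
#' @export
median_split <- function(labels) {
  if (!all(c("participant", "n1_rt") %in% names(labels)))
    stop("`labels` must come from label_sequences()")
  med <- stats::ave(labels$n1_rt, labels$participant, FUN = stats::median)
  labels$n1_speed <- ifelse(labels$n1_rt < med, "fast", "slow")
  labels
}

#' Per-participant cell means and N-2 repetition costs
#'
#' Computes, per participant and stratum, the mean target RT in the N-2
#' repetition and N-2 switch cells and their difference (the N-2 repetition
#' cost, repetition minus switch). A cost is defined only where both cells
#' are non-empty; otherwise it is `NA`.
#'
#' @param labels Labelled targets ([label_sequences()], usually after
#'   [median_split()]).
#' @param strata Character vector of label columns defining the strata
#'   (default `c("n2_category", "n1_speed")`; use e.g. `"n2_latent"`
#'   against simulated data).
#' @return List with `cells` (participant, strata, seq_type, n, mean_rt) and
#'   `costs` (participant, strata, n2_cost).
#' @export
cost_table <- function(labels, strata = c("n2_category", "n1_speed")) {
  if (!all(strata %in% names(labels)))
    stop("missing strata columns: ",
         paste(setdiff(strata, names(labels)), collapse = ", "))
  by <- c("participant", strata, "seq_type")
  agg_n <- stats::aggregate(labels$rt_ms, labels[by], length)
  agg_m <- stats::aggregate(labels$rt_ms, labels[by], mean)
  cells <- agg_m
  names(cells)[ncol(cells)] <- "mean_rt"
  cells$n <- agg_n$x
  wide_by <- c("participant", strata)
  rep_cells <- cells[cells$seq_type == "n2_repetition", c(wide_by, "mean_rt")]
  swi_cells <- cells[cells$seq_type == "n2_switch", c(wide_by, "mean_rt")]
  costs <- merge(rep_cells, swi_cells, by = wide_by, all = TRUE,
                 suffixes = c("_rep", "_swi"))
  costs$n2_cost <- costs$mean_rt_rep - costs$mean_rt_swi
  list(cells = cells[order(cells$participant), ],
       costs = costs[order(costs$participant), ])
}

#' Repeated-measures ANOVA on participant cell means
#'
#' Fully within-subject ANOVA on one observation per participant and cell
#' (the participant cell means), for balanced complete designs.
#' Participants with any missing cell are dropped. Sums of squares come
#' from the classical stratified decomposition (each effect tested against
#' its interaction with participants). Reports, per effect: F, degrees of
#' freedom, p, partial eta squared (effect SS over effect + its error SS)
#' and generalized eta squared (effect SS over effect SS plus *all* error
#' strata SS, including the participant stratum). No sphericity correction
#' is applied (intended for 2-level factors, where none is needed).
#'
#' @param data Long data frame of cell means.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the participant column.
#' @return An object of class `rm_anova`: data frame with columns `effect`,
#'   `df_num`, `df_den`, `F`, `p`, `pes`, `ges`.
#' @export
rm_anova <- function(data, dv = "n2_cost", within, subject = "participant") {
  cols <- c(subject, within, dv)
  if (!all(cols %in% names(data)))
    stop("missing columns: ", paste(setdiff(cols, names(data)), collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols]
  # keep only participants with a complete crossing
  n_cells <- prod(vapply(within, function(f) length(unique(d[[f]])), numeric(1)))
  cnt <- table(d[[subject]])
  keep <- names(cnt)[cnt == n_cells]
  d <- d[d[[subject]] %in% keep, ]
  if (length(keep) < 2L) stop("need at least 2 participants with complete cells")
  d[[subject]] <- factor(d[[subject]])
  for (f in within) d[[f]] <- factor(d[[f]])
  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(
    sprintf("%s ~ %s + Error(%s/(%s))", dv, rhs, subject, rhs))
  fit <- stats::aov(form, data = d)
  s <- summary(fit)
  # collect (SS, df) per effect and per error stratum
  eff <- list(); resid_ss <- 0; subj_ss <- NA_real_
  for (stratum in s) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    r <- which(terms == "Residuals")
    if (length(r)) resid_ss <- resid_ss + tab[r, "Sum Sq"]
    for (j in setdiff(seq_len(nrow(tab)), r)) {
      eff[[terms[j]]] <- list(ss = tab[j, "Sum Sq"], df = tab[j, "Df"],
                              ss_err = tab[r, "Sum Sq"],
                              df_err = tab[r, "Df"])
    }
  }
  total_ss <- resid_ss + sum(vapply(eff, `[[`, numeric(1), "ss"))
  eps <- 1e-12 * max(total_ss, 1)  # clamp numerically-zero effect SS
  out <- do.call(rbind, lapply(names(eff), function(e) {
    x <- eff[[e]]
    if (x$ss < eps) {
      return(data.frame(effect = e, df_num = x$df, df_den = x$df_err,
                        F = 0, p = 1, pes = 0, ges = 0,
                        stringsAsFactors = FALSE))
    }
    Fv <- (x$ss / x$df) / (x$ss_err / x$df_err)
    data.frame(effect = e, df_num = x$df, df_den = x$df_err, F = Fv,
               p = stats::pf(Fv, x$df, x$df_err, lower.tail = FALSE),
               pes = x$ss / (x$ss + x$ss_err),
               ges = x$ss / (x$ss + resid_ss),
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_subjects") <- length(keep)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Paired contrast with Cohen's dz
#'
#' Paired t test on difference scores; dz is the mean of the differences
#' divided by their standard deviation.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` to treat `x` as
#'   precomputed differences.
#' @return List: `t`, `df`, `p`, `dz`, `mean_diff`.
#' @examples
#' paired_contrast(c(1, 2, 3))  # dz = 2
#' @export
paired_contrast <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("need at least 2 paired observations")
  m <- mean(d); s <- stats::sd(d); n <- length(d)
  tv <- m / (s / sqrt(n))
  list(t = tv, df = n - 1L,
       p = 2 * stats::pt(abs(tv), n - 1L, lower.tail = FALSE),
       dz = m / s, mean_diff = m)
}

#' Two-sample permutation test on the difference of means
#'
#' Two-sided test of the difference in group means of two independent
#' samples of per-participant values. When the number of distinct group
#' assignments `choose(n_a + n_b, n_a)` does not exceed `exact_limit`, all
#' assignments are enumerated and the p value is the exact proportion whose
#' absolute mean difference is at least the observed one (the identity
#' assignment counts). Otherwise `n_perm` Monte-Carlo assignments are drawn
#' and the identity assignment is included:
#' p = (1 + #extreme) / (n_perm + 1).
#'
#' @param group_a,group_b Numeric vectors.
#' @param n_perm Monte-Carlo sample size.
#' @param seed Optional integer seed (Monte-Carlo mode).
#' @param exact_limit Enumeration threshold on the number of assignments.
#' @return List: `p`, `observed` (mean_a - mean_b), `method`
#'   (`"exact"`/`"monte_carlo"`), `n_used`.
#' @examples
#' permutation_test(c(1, 2), c(3, 4))$p  # 1/3
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000, seed = NULL,
                             exact_limit = 20000) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  tol <- 1e-12 * max(1, abs(obs))
  n_arr <- choose(na + nb, na)
  if (n_arr <= exact_limit) {
    idx <- utils::combn(na + nb, na)
    tot <- sum(pooled)
    diffs <- apply(idx, 2, function(j)
      mean(pooled[j]) - (tot - sum(pooled[j])) / nb)
    p <- mean(abs(diffs) >= abs(obs) - tol)
    list(p = p, observed = obs, method = "exact", n_used = n_arr)
  } else {
    with_seed(seed, {
      extreme <- 0L
      for (k in seq_len(n_perm)) {
        j <- sample.int(na + nb, na)
        dm <- mean(pooled[j]) - mean(pooled[-j])
        if (abs(dm) >= abs(obs) - tol) extreme <- extreme + 1L
      }
      list(p = (1 + extreme) / (n_perm + 1), observed = obs,
           method = "monte_carlo", n_used = n_perm)
    })
  }
}
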