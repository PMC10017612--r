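test_that("triplet labels and context follow the definitions", {
  # 10-trial toy block, one N-2 error, hand-enumerated expectations
  tasks <- c("a", "b", "a", "c", "a", "b", "c", "b", "a", "b")
  correct <- rep(TRUE, 10); correct[4] <- FALSE
  rt <- seq(500, 590, by = 10)
  tr <- toy_trials(correct, rt, task = tasks)
  tr$stim_id <- paradigms$three_key$stimuli$stim_id[1:10]
  tr$category <- ifelse(correct, "correct", "task_confusion")
  out <- label_sequences(trim_trials(tr, trim_config()))
  # trial 5 follows the error at 4 (post_error); eligible targets: 3..10
  # minus {5}; of those, trial 6 has an N-2 error context at trial 4
  expect_setequal(out$trial, c(3, 6, 7, 8, 9, 10))
  expect_equal(out$seq_type[out$trial == 3], "n2_repetition")   # a b a
  expect_equal(out$seq_type[out$trial == 6], "n2_switch")       # c a b
  expect_equal(out$seq_type[out$trial == 7], "n2_switch")       # a b c
  expect_equal(out$seq_type[out$trial == 8], "n2_repetition")   # b c b
  expect_equal(out$seq_type[out$trial == 9], "n2_switch")       # c b a
  expect_equal(out$seq_type[out$trial == 10], "n2_repetition")  # b a b
  expect_equal(out$n2_category[out$trial == 6], "task_confusion")
  expect_true(all(out$n2_category[out$trial != 6] == "correct"))
  expect_equal(out$n1_rt, rt[out$trial - 1])
})

test_that("targets whose N-1 trial was an error are excluded", {
  tasks <- rep(c("a", "b", "c"), length.out = 9)
  correct <- rep(TRUE, 9); correct[5] <- FALSE
  tr <- toy_trials(correct, rep(500, 9), task = tasks)
  tr$category <- ifelse(correct, "correct", "response_confusion")
  out <- label_sequences(trim_trials(tr, trim_config()))
  expect_false(6 %in% out$trial)  # trial 6 follows the N-1 error at 5
  expect_true(7 %in% out$trial)   # error at N-2 is fine
})

test_that("median split halves the targets and sends ties to slow", {
  lab <- data.frame(participant = 1, n1_rt = 1:10)
  out <- median_split(lab)
  expect_equal(out$n1_speed, rep(c("fast", "slow"), each = 5))
  tied <- median_split(data.frame(participant = 1, n1_rt = rep(7, 4)))
  expect_true(all(tied$n1_speed == "slow"))
  # per-participant, not pooled
  two <- median_split(data.frame(participant = rep(1:2, each = 4),
                                 n1_rt = c(1:4, 101:104)))
  expect_equal(sum(two$n1_speed == "fast"), 4)
})

test_that("cost table is repetition minus switch per stratum", {
  lab <- expand.grid(participant = 1:2,
                     seq_type = c("n2_repetition", "n2_switch"),
                     n2_category = c("correct", "task_confusion"),
                     stringsAsFactors = FALSE)
  lab$rt_ms <- ifelse(lab$seq_type == "n2_repetition", 500, 470)
  ct <- cost_table(lab, strata = "n2_category")
  expect_true(all(ct$costs$n2_cost == 30))
  # identical means give zero cost
  lab$rt_ms <- 500
  expect_true(all(cost_table(lab, strata = "n2_category")$costs$n2_cost == 0))
  # empty cell yields NA cost
  lab2 <- lab[!(lab$participant == 1 & lab$seq_type == "n2_switch" &
                lab$n2_category == "correct"), ]
  ct2 <- cost_table(lab2, strata = "n2_category")
  expect_true(is.na(ct2$costs$n2_cost[ct2$costs$participant == 1 &
                                      ct2$costs$n2_category == "correct"]))
})

test_that("rm_anova matches a hand-computed 2x2 within-subject oracle", {
  # 4 participants x 2 x 2, textbook sums of squares computed independently
  d <- expand.grid(participant = 1:4, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  set.seed(77)
  d$y <- c(10, 12, 14, 16,  13, 15, 18, 19,
           11, 13, 15, 17,  16, 19, 22, 24)
  # --- oracle: classical decomposition from marginal means ---
  gm <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mS <- tapply(d$y, d$participant, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  mAS <- tapply(d$y, list(d$A, d$participant), mean)
  mBS <- tapply(d$y, list(d$B, d$participant), mean)
  ssA <- 8 * sum((mA - gm)^2); ssB <- 8 * sum((mB - gm)^2)
  ssS <- 4 * sum((mS - gm)^2)
  ssAB <- 4 * sum((sweep(sweep(mAB, 1, mA), 2, mB) + gm)^2)
  ssAS <- 2 * sum((sweep(sweep(mAS, 1, mA), 2, mS) + gm)^2)
  ssBS <- 2 * sum((sweep(sweep(mBS, 1, mB), 2, mS) + gm)^2)
  ssT <- sum((d$y - gm)^2)
  ssABS <- ssT - ssA - ssB - ssS - ssAB - ssAS - ssBS
  out <- rm_anova(d, dv = "y", within = c("A", "B"))
  rowA <- out[out$effect == "A", ]
  expect_equal(rowA$F, (ssA / 1) / (ssAS / 3), tolerance = 1e-10)
  expect_equal(rowA$pes, ssA / (ssA + ssAS), tolerance = 1e-10)
  expect_equal(rowA$ges, ssA / (ssA + ssS + ssAS + ssBS + ssABS),
               tolerance = 1e-10)
  rowAB <- out[out$effect == "A:B", ]
  expect_equal(rowAB$F, (ssAB / 1) / (ssABS / 3), tolerance = 1e-10)
  expect_equal(rowAB$df_num, 1)
  expect_equal(rowAB$df_den, 3)
})

test_that("equal cell means give F = 0 and fewer than 2 subjects fail", {
  d <- expand.grid(participant = 1:3, A = c("a1", "a2"),
                   stringsAsFactors = FALSE)
  d$y <- rep(c(5, 6, 7), 2)  # no A effect, only subject variance
  out <- rm_anova(d, dv = "y", within = "A")
  expect_equal(out$F, 0)
  expect_error(rm_anova(d[d$participant == 1, ], dv = "y", within = "A"),
               "2 participants")
})

test_that("paired contrast: diffs (1,2,3) give dz = 2", {
  pc <- paired_contrast(c(1, 2, 3))
  expect_equal(pc$dz, 2)
  expect_equal(pc$mean_diff, 2)
  expect_equal(pc$t, 2 * sqrt(3))
})

test_that("permutation test: exact enumeration on small groups", {
  expect_equal(permutation_test(c(1, 2), c(3, 4))$p, 1 / 3)
  same <- permutation_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)
  expect_equal(same$method, "exact")
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("permutation p is invariant to label swap and location shift", {
  set.seed(88)
  a <- rnorm(6); b <- rnorm(7, mean = 1)
  p1 <- permutation_test(a, b)$p
  expect_equal(permutation_test(b, a)$p, p1)
  expect_equal(permutation_test(a + 10, b + 10)$p, p1)
})

test_that("Monte-Carlo p approximates the exact p", {
  set.seed(99)
  a <- rnorm(5); b <- rnorm(5, 1)
  ex <- permutation_test(a, b)$p
  mc <- permutation_test(a, b, n_perm = 4000, seed = 7, exact_limit = 1)$p
  se <- sqrt(ex * (1 - ex) / 4000)
  expect_lt(abs(mc - ex), 3 * se + 1 / 4001)
})

test_that("generative dissociation: injected cost recovered by stratum", {
  # moderate size here; the full-scale check lives in test-acceptance.R
  p3 <- paradigms$three_key
  base <- list(T = 0.85, R = 0.9, delta_n2 = 40, pes = 60, kappa = 1)
  never <- latent_params(T = base$T, R = base$R, delta_n2 = 40, pes = 60,
                         tau = Inf, kappa = 1, timeout_ms = NULL)
  always <- latent_params(T = base$T, R = base$R, delta_n2 = 40, pes = 60,
                          tau = -Inf, kappa = 1, timeout_ms = NULL)
  for (cfgi in list(list(lp = never, tsf = 0), list(lp = always, tsf = 40))) {
    tr <- simulate_experiment(p3, 40, 4, 100, cfgi$lp, seed = 55)
    lab <- median_split(label_sequences(trim_trials(tr, trim_config())))
    ct <- cost_table(lab, strata = "n2_latent")
    m <- tapply(ct$costs$n2_cost, ct$costs$n2_latent, mean, na.rm = TRUE)
    expect_lt(abs(m[["correct"]] - 40), 15)
    expect_lt(abs(m[["task_selection_failure"]] - cfgi$tsf), 15)
  }
})
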