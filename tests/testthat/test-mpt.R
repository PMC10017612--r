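test_that("category probabilities match branch-enumeration values", {
  # exp2 incongruent at (0.8, 0.9): TR = 0.72, (1-T)(1-R)/2 = 0.01
  p <- category_probabilities("exp2_congruency", 0.8, 0.9)
  expect_equal(p$correct_incongruent, 0.73)
  expect_equal(p$error_incongruent, 0.27)
  # exp3 at (0.9, 0.8)
  p <- category_probabilities("exp3_three_key", 0.9, 0.8)
  expect_equal(as.numeric(p), c(0.73, 0.17, 0.10))
  # degenerate corner
  for (m in c("exp2_congruency", "exp3_three_key")) {
    p <- category_probabilities(m, 1, 1)
    expect_equal(as.numeric(p[grep("^correct", names(p))]),
                 rep(1, length(grep("^correct", names(p)))))
    expect_equal(sum(p[grep("^error|confusion", names(p))]), 0)
  }
  expect_error(category_probabilities("exp3_three_key", -0.1, 0.5), "\\[0, 1\\]")
})

test_that("category probabilities sum to 1 within each stratum", {
  set.seed(101)
  TT <- runif(10000); RR <- runif(10000)
  p2 <- category_probabilities("exp2_congruency", TT, RR)
  expect_lt(max(abs(p2$correct_congruent + p2$error_congruent - 1)), 1e-12)
  expect_lt(max(abs(p2$correct_incongruent + p2$error_incongruent - 1)), 1e-12)
  p3 <- category_probabilities("exp3_three_key", TT, RR)
  expect_lt(max(abs(rowSums(p3) - 1)), 1e-12)
})

test_that("MLE recovers generating parameters from exact expected counts", {
  f <- fit_mpt(c(correct = 7300, task_confusion = 1700,
                 response_confusion = 1000), "exp3_three_key")
  expect_equal(f$T_hat, 0.9, tolerance = 1e-6)
  expect_equal(f$R_hat, 0.8, tolerance = 1e-6)
  expect_lt(f$G2, 1e-6)
  expect_false(f$boundary)
  expect_identical(f$df, 0L)

  cnts <- round(10000 * as.numeric(
    category_probabilities("exp2_congruency", 0.85, 0.9)))
  names(cnts) <- c("correct_congruent", "error_congruent",
                   "correct_incongruent", "error_incongruent")
  f2 <- fit_mpt(cnts, "exp2_congruency")
  expect_equal(f2$T_hat, 0.85, tolerance = 1e-3)
  expect_equal(f2$R_hat, 0.9, tolerance = 1e-3)
})

test_that("all-correct counts hit the boundary with G2 = 0", {
  f <- fit_mpt(c(correct = 500, task_confusion = 0,
                 response_confusion = 0), "exp3_three_key")
  expect_equal(f$T_hat, 1, tolerance = 1e-6)
  expect_equal(f$R_hat, 1, tolerance = 1e-6)
  expect_true(f$boundary)
  expect_equal(f$G2, 0)
})

test_that("MLE matches the 1001x1001 grid-search oracle", {
  set.seed(202)
  for (m in c("exp3_three_key", "exp2_congruency")) {
    for (rep in 1:10) {
      tt <- runif(1, 0.55, 0.98); rr <- runif(1, 0.55, 0.98)
      pr <- as.numeric(category_probabilities(m, tt, rr))
      cats <- names(category_probabilities(m, 0.5, 0.5))
      if (m == "exp2_congruency") {
        cnt <- c(as.numeric(rmultinom(1, 1500, pr[1:2])),
                 as.numeric(rmultinom(1, 1500, pr[3:4])))
      } else {
        cnt <- as.numeric(rmultinom(1, 3000, pr))
      }
      names(cnt) <- cats
      f <- fit_mpt(cnt, m)
      g <- grid_mle(as.list(cnt), m)
      expect_lt(abs(f$T_hat - g["T"]), 1e-3)
      expect_lt(abs(f$R_hat - g["R"]), 1e-3)
    }
  }
})

test_that("saturated-model property: interior MLE reproduces proportions", {
  set.seed(303)
  for (rep in 1:5) {
    cnt <- as.numeric(rmultinom(1, 2000,
      as.numeric(category_probabilities("exp3_three_key",
                                        runif(1, 0.7, 0.95),
                                        runif(1, 0.7, 0.95)))))
    names(cnt) <- c("correct", "task_confusion", "response_confusion")
    f <- fit_mpt(cnt, "exp3_three_key")
    if (!f$boundary) {
      fitted <- as.numeric(category_probabilities("exp3_three_key",
                                                  f$T_hat, f$R_hat))
      expect_equal(fitted, unname(cnt / sum(cnt)), tolerance = 1e-4)
      expect_lt(f$G2, 1e-6)
    }
  }
})

test_that("invalid count inputs are rejected", {
  expect_error(fit_mpt(c(correct = 0, task_confusion = 0,
                         response_confusion = 0), "exp3_three_key"), "zero")
  expect_error(fit_mpt(c(a = 1, b = 2), "exp3_three_key"), "categories")
  expect_error(fit_mpt(c(correct_congruent = 10, error_congruent = 5,
                         correct_incongruent = 0, error_incongruent = 0),
                       "exp2_congruency"), "strata")
})

test_that("conditional failure probabilities follow the tree ratios", {
  # exp3 at (0.9, 0.8): p(tsf | TC) = 0.08 / 0.17, p(tsf | RC) = 0.1
  cp <- conditional_failure_probs("exp3_three_key", 0.9, 0.8)
  expect_equal(cp$p_tsf_given_TC, 0.08 / 0.17)
  expect_equal(cp$p_tsf_given_RC, 0.1)
  # T = 1: no task-selection failures exist
  for (m in c("exp2_congruency", "exp3_three_key")) {
    cp <- conditional_failure_probs(m, 1, 0.8)
    expect_equal(cp$p_tsf_given_TC, 0)
    expect_equal(cp$p_tsf_given_RC, 0)
  }
  # undefined at zero-probability categories
  cp <- conditional_failure_probs("exp3_three_key", 1, 1)
  expect_true(is.na(cp$p_tsf_given_TC))
  expect_true(is.na(cp$p_tsf_given_RC))
})

test_that("p(tsf | RC) equals 1 - T on a grid, and p(tsf | TC) decreases in T", {
  g <- expand.grid(T = seq(0.05, 0.95, by = 0.05),
                   R = seq(0.05, 0.95, by = 0.05))
  cp3 <- conditional_failure_probs("exp3_three_key", g$T, g$R)
  expect_equal(cp3$p_tsf_given_RC, 1 - g$T, tolerance = 1e-12)
  cp2 <- conditional_failure_probs("exp2_congruency", g$T, g$R)
  expect_equal(cp2$p_tsf_given_RC, 1 - g$T, tolerance = 1e-12)
  for (r in c(0.3, 0.6, 0.9)) {
    ts <- seq(0.05, 0.95, by = 0.05)
    v <- conditional_failure_probs("exp3_three_key", ts, r)$p_tsf_given_TC
    expect_true(all(diff(v) < 0))
  }
})

test_that("univalent direct estimators match the printed definitions", {
  out <- exp1_failure_probs(c(correct = 900, response_confusion = 50,
                              task_confusion = 30, mixed = 20))
  expect_equal(out$p_task_selection_failure, 0.05)
  expect_equal(out$p_task_execution_failure, 0.07)
  out0 <- exp1_failure_probs(c(correct = 10, response_confusion = 0,
                               task_confusion = 0, mixed = 0))
  expect_equal(out0$p_task_selection_failure, 0)
  expect_equal(out0$p_task_execution_failure, 0)
  expect_error(exp1_failure_probs(c(correct = 0, response_confusion = 0,
                                    task_confusion = 0, mixed = 0)), "trials")
})
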