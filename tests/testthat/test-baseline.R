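test_that("baseline model recovers trivial means and variances", {
  pow <- array(3, dim = c(4, 2, 3, 75))
  tf <- make_tfr(pow)
  b <- fit_baseline(tf)
  expect_true(all(b$M == 3))
  expect_true(all(b$S2 == 0))
  expect_equal(b$n, 4)
  # two trials with prestimulus means 1 and 3 -> M = 2
  pow2 <- array(0, dim = c(2, 1, 1, 75))
  tf2 <- make_tfr(pow2)
  bl <- tf2$times >= -0.7 & tf2$times <= -0.2
  pow2[1, 1, 1, bl] <- 1
  pow2[2, 1, 1, bl] <- 3
  tf2$power <- pow2
  expect_equal(unname(fit_baseline(tf2)$M[1, 1]), 2)
  expect_error(fit_baseline(make_tfr(array(1, dim = c(1, 1, 1, 75)))), "2 trials")
})

test_that("baseline M and S2 match a direct loop recomputation", {
  set.seed(3)
  pow <- array(rexp(6 * 2 * 3 * 75), dim = c(6, 2, 3, 75))
  tf <- make_tfr(pow)
  b <- fit_baseline(tf)
  bl <- which(tf$times >= -0.7 & tf$times <= -0.2)
  act <- which(tf$times >= 0 & tf$times <= 3)
  for (ch in 1:2) for (fr in 1:3) {
    expect_equal(unname(b$M[ch, fr]), mean(pow[, ch, fr, bl]))
    for (k in seq_along(act))
      expect_equal(unname(b$S2[ch, fr, k]), var(pow[, ch, fr, act[k]]))
  }
})

test_that("condition t-map is the one-sample t against the fixed baseline mean", {
  pow <- array(0, dim = c(4, 1, 1, 75))
  tf <- make_tfr(pow)
  bl <- tf$times >= -0.7 & tf$times <= -0.2
  act <- tf$times >= 0
  M <- 5
  pow[, 1, 1, bl] <- M
  pow[, 1, 1, act] <- M + c(1, 1, 1, 3)  # mean diff 1.5, sd 1, n 4 -> t = 3
  tf$power <- pow
  tf$events$outcome <- "pair"
  b <- fit_baseline(tf)
  tm <- condition_tmap(tf, b, "pair")
  expect_equal(unname(tm$t[1, 1, 1]), 1.5 / (1 / sqrt(4)))
  expect_equal(unname(tm$t[1, 1, 1]), 3.0)
  # all condition trials equal to M -> t = 0 (with degeneracy warning)
  pow[, 1, 1, act] <- M
  tf$power <- pow
  b2 <- fit_baseline(tf)
  expect_warning(tm0 <- condition_tmap(tf, b2, "pair"), "zero")
  expect_true(all(tm0$t == 0))
})

test_that("negating power deviations negates the condition t-map", {
  set.seed(8)
  pow <- array(rnorm(8 * 2 * 2 * 75, mean = 10), dim = c(8, 2, 2, 75))
  tf <- make_tfr(pow)
  b <- fit_baseline(tf)
  tm <- condition_tmap(tf, b, rep(TRUE, 8))
  # reflect all trials around the baseline mean M
  pow_neg <- pow
  for (ch in 1:2) for (fr in 1:2)
    pow_neg[, ch, fr, ] <- 2 * b$M[ch, fr] - pow[, ch, fr, ]
  tf_neg <- make_tfr(pow_neg)
  b_neg <- fit_baseline(tf_neg)
  expect_equal(b_neg$M, b$M, tolerance = 1e-12)
  tm_neg <- condition_tmap(tf_neg, b_neg, rep(TRUE, 8))
  expect_equal(tm_neg$t, -tm$t, tolerance = 1e-10)
})

test_that("single-trial t equals the elementwise formula and its invariances", {
  set.seed(9)
  pow <- array(rexp(5 * 2 * 3 * 75), dim = c(5, 2, 3, 75))
  tf <- make_tfr(pow)
  b <- fit_baseline(tf)
  st <- single_trial_t(tf, b)
  # brute-force elementwise oracle for t = (pow - M) / sqrt(S2 / n)
  act <- which(tf$times >= 0 & tf$times <= 3)
  for (tr in 1:5) for (ch in 1:2) for (fr in 1:3) for (k in c(1, 30, 61)) {
    want <- (pow[tr, ch, fr, act[k]] - mean(pow[, ch, fr, tf$times >= -0.7 & tf$times <= -0.2])) /
      sqrt(var(pow[, ch, fr, act[k]]) / 5)
    expect_equal(unname(st$t[tr, ch, fr, k]), want, tolerance = 1e-12)
  }
  # common rescaling of all trials cancels
  tf_scaled <- make_tfr(pow * 7.3)
  st_scaled <- single_trial_t(tf_scaled, fit_baseline(tf_scaled))
  expect_equal(st_scaled$t, st$t, tolerance = 1e-10)
  # pow = M -> t = 0 and monotonicity in pow
  i <- which.max(st$t[, 1, 1, 1])
  expect_gt(pow[i, 1, 1, act[1]], min(pow[, 1, 1, act[1]]))
})

test_that("single-trial t follows (pow - M)/sqrt(S2/n) for a hand-built case", {
  pow <- array(1, dim = c(4, 1, 1, 75))
  tf <- make_tfr(pow)
  act <- tf$times >= 0
  pow[, 1, 1, act] <- c(1, 1 + 4 / sqrt(6), 1 - 4 / sqrt(6), 3)
  # chosen so M = 1 (baseline all ones), trial-4 deviation = 2, S2 = var = 4
  tf$power <- pow
  b <- fit_baseline(tf)
  expect_equal(unname(b$S2[1, 1, 1]), var(pow[, 1, 1, which(act)[1]]))
  st <- single_trial_t(tf, b)
  expect_equal(unname(st$t[4, 1, 1, 1]),
               2 / sqrt(unname(b$S2[1, 1, 1]) / 4), tolerance = 1e-12)
})

test_that("trial-averaged single-trial t relates to the condition t-map algebraically", {
  set.seed(10)
  pow <- array(rexp(6 * 1 * 2 * 75), dim = c(6, 1, 2, 75))
  tf <- make_tfr(pow)
  tf$events$outcome <- rep(c("pair", "miss"), each = 3)
  b <- fit_baseline(tf)
  st <- single_trial_t(tf, b)
  tm <- condition_tmap(tf, b, "pair")
  sel <- tf$events$outcome == "pair"
  act <- which(tf$times >= 0 & tf$times <= 3)
  mean_st <- apply(st$t[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  # exact relation: mean(single-trial t) * sqrt(S2/n_all) = t_cond * sd_cond/sqrt(n_cond)
  for (fr in 1:2) for (k in c(1, 25)) {
    sd_cond <- sd(pow[sel, 1, fr, act[k]])
    lhs <- mean_st[1, fr, k] * sqrt(b$S2[1, fr, k] / b$n)
    rhs <- tm$t[1, fr, k] * sd_cond / sqrt(sum(sel))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("zero across-trial variance makes the single-trial statistic an error", {
  pow <- array(2, dim = c(3, 1, 1, 75))
  tf <- make_tfr(pow)
  b <- fit_baseline(tf)
  expect_error(single_trial_t(tf, b), "variance")
})
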