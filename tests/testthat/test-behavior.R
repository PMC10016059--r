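rec <- function(condition, item_is_old = TRUE, item_response = NA,
                pair_is_correct = NA) {
  data.frame(subject = "s1", condition = condition, item_is_old = item_is_old,
             item_response = item_response, pair_response = NA,
             pair_is_correct = pair_is_correct, stringsAsFactors = FALSE)
}

test_that("categorize maps responses to memory outcomes", {
  records <- rbind(
    rec("match", item_response = "new"),                       # miss
    rec("mismatch", item_response = "old", pair_is_correct = FALSE),  # item_only
    rec("match", item_response = "old", pair_is_correct = TRUE),      # pair
    rec("old_new", item_response = "old"),                     # excluded cond
    rec("new_old", item_is_old = FALSE, item_response = "new"),# excluded cond
    rec("match", item_response = NA)                           # missing response
  )
  out <- categorize(records)
  expect_equal(as.character(out),
               c("miss", "item_only", "pair", "excluded", "excluded", "excluded"))
  # total and idempotent: re-categorizing the same records gives the same result
  expect_identical(out, categorize(records))
  expect_false(anyNA(out))
})

test_that("chance threshold reproduces 0.31 for the study design and rescales", {
  d <- generate_design(50, seed = 2)
  p <- sim_params(n_scenes = 50)
  m <- simulate_behavior(d, p, seed = 3)
  r <- simulate_responses(d, m, p, seed = 4)
  cc <- item_chance_check(r)
  expect_equal(cc$threshold, 0.5 * 250 / 400)
  expect_equal(round(cc$threshold, 2), 0.31)
  # half-size design: 125 old of 200 -> same threshold
  d2 <- generate_design(25, seed = 5)
  m2 <- simulate_behavior(d2, sim_params(n_scenes = 25), seed = 6)
  r2 <- simulate_responses(d2, m2, sim_params(n_scenes = 25), seed = 7)
  expect_equal(item_chance_check(r2)$threshold, 0.5 * 125 / 200)
})

test_that("accuracy exactly at threshold is excluded; perfect accuracy kept", {
  # constructed set: 16 old of 32 trials -> threshold 0.25; 4/16 correct = 0.25
  records <- rbind(
    do.call(rbind, replicate(16, rec("match", item_response = "new"), simplify = FALSE)),
    do.call(rbind, replicate(16, rec("new_new", item_is_old = FALSE,
                                     item_response = "new"), simplify = FALSE))
  )
  records$item_response[1:4] <- "old"
  cc <- item_chance_check(records)
  expect_equal(cc$threshold, 0.25)
  expect_equal(cc$accuracy, 0.25)
  expect_false(cc$keep)
  records$item_response[records$item_is_old] <- "old"
  cc2 <- item_chance_check(records)
  expect_equal(cc2$accuracy, 1)
  expect_true(cc2$keep)
})

test_that("minimum-trial filter keeps only subjects with >= 10 trials everywhere", {
  expect_true(min_trial_filter(c(10, 22, 59)))
  expect_false(min_trial_filter(c(9, 50, 50)))
  expect_false(min_trial_filter(c(0, 0, 0)))
})

test_that("per-subject response rates sum to one", {
  ev <- simulate_events(sim_params(n_subjects = c(younger = 3L, older = 3L),
                                   n_scenes = 10L), seed = 9)
  ev <- ev[ev$condition %in% c("match", "mismatch"), ]
  rates <- response_rates(ev)
  expect_equal(rates$miss + rates$item_only + rates$pair, rep(1, nrow(rates)))
  expect_equal(nrow(rates), 6)
})

test_that("mixed ANOVA matches textbook sums of squares and handles ties", {
  set.seed(31)
  rates <- data.frame(
    subject = sprintf("s%02d", 1:12),
    age_group = rep(c("younger", "older"), each = 6),
    miss = runif(12, 0.1, 0.3), item_only = runif(12, 0.2, 0.4),
    pair = runif(12, 0.4, 0.6)
  )
  got <- rate_anova(rates)
  want <- ref_mixed_anova(rates)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2)
  # no variance anywhere -> all F zero
  flat <- rates
  flat$miss <- 1 / 3; flat$item_only <- 1 / 3; flat$pair <- 1 / 3
  got_flat <- rate_anova(flat)
  expect_equal(got_flat$F, c(0, 0, 0))
  # identical triplets with a real level effect but zero residual
  det <- rates
  det$miss <- 0.2; det$item_only <- 0.3; det$pair <- 0.5
  got_det <- rate_anova(det)
  expect_equal(got_det$F[got_det$effect == "age"], 0)
  expect_equal(got_det$F[got_det$effect == "memory_level"], Inf)
})

test_that("ANOVA detects a pure memory-level effect and not a spurious age effect", {
  set.seed(55)
  hits_level <- 0; hits_age <- 0
  for (r in 1:10) {
    base <- c(0.2, 0.33, 0.47)
    rates <- data.frame(
      subject = sprintf("s%02d", 1:40),
      age_group = rep(c("younger", "older"), each = 20),
      miss = base[1] + rnorm(40, 0, 0.03),
      item_only = base[2] + rnorm(40, 0, 0.03),
      pair = base[3] + rnorm(40, 0, 0.03)
    )
    a <- rate_anova(rates)
    hits_level <- hits_level + (a$p[a$effect == "memory_level"] < 0.05)
    hits_age <- hits_age + (a$p[a$effect == "age"] < 0.05)
  }
  expect_equal(hits_level, 10)
  expect_lte(hits_age, 2)
})

test_that("interaction F under permuted group labels follows its F reference", {
  set.seed(77)
  rates <- data.frame(
    subject = sprintf("s%02d", 1:20),
    age_group = rep(c("younger", "older"), each = 10),
    miss = runif(20, 0.1, 0.3), item_only = runif(20, 0.2, 0.4),
    pair = runif(20, 0.4, 0.6)
  )
  fstats <- replicate(300, {
    perm <- rates
    perm$age_group <- sample(perm$age_group)
    a <- rate_anova(perm)
    a$F[a$effect == "age:memory_level"]
  })
  ks <- suppressWarnings(stats::ks.test(fstats, "pf", 2, 36))
  expect_gt(ks$p.value, 0.01)
})
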