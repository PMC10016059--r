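test_that("Gauss-Hermite rule integrates Gaussian moments exactly", {
  gh <- gauss_hermite(10)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^8), sqrt(pi) * 105 / 16, tolerance = 1e-9)
  expect_equal(sum(gh$weights * gh$nodes), 0, tolerance = 1e-12)
})

test_that("zero random-effect variance reduces to ordinary logistic regression", {
  # note beta positions: (Intercept), theta, ageolder, alpha — age effect 0 so
  # subjects are exchangeable and the true random-intercept variance is 0
  d <- simulate_glmm_frame(20, 40, beta = c(0.3, 0.5, 0, -0.7), sigma = 0, seed = 21)
  ref <- glm(y ~ theta + alpha, family = binomial(), data = d)
  X <- model.matrix(~ theta + alpha, d)
  Xs <- lapply(split(seq_len(nrow(d)), d$subject), function(i) X[i, , drop = FALSE])
  ys <- split(d$y, d$subject)
  gh <- gauss_hermite(10)
  # in the sigma -> 0 limit the AGQ marginal likelihood is the GLM likelihood
  nll0 <- oscsme:::agq_nll(c(coef(ref), -12), Xs, ys, gh)
  expect_equal(nll0, -as.numeric(logLik(ref)), tolerance = 1e-8)
  # and maximizing it over the fixed effects recovers the GLM estimates
  opt <- optim(rep(0, 3), function(b) oscsme:::agq_nll(c(b, -12), Xs, ys, gh),
               method = "BFGS", control = list(reltol = 1e-12))
  expect_lt(max(abs(opt$par - coef(ref))), 1e-3)
  # the free fit drifts to a small boundary estimate on such data
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 10)
  expect_lt(fit$sigma, 0.2)
  expect_lt(max(abs(coef(fit) - coef(ref))), 0.05)
})

test_that("AGQ marginal likelihood matches dense numerical integration", {
  d <- simulate_glmm_frame(15, 25, beta = c(0.2, 0.4, -0.5), sigma = 0.6, seed = 22)
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 10)
  X <- model.matrix(~ theta + alpha, d)
  ref_ll <- ref_marginal_loglik(coef(fit), fit$sigma, X, d$y, d$subject)
  expect_lt(abs(fit$logLik - ref_ll), 1e-4)
  # Laplace (1 node) differs from 10-node AGQ, and 10-node is closer to truth
  fit1 <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 1)
  ll1_at_10 <- -oscsme:::agq_nll(
    c(coef(fit), log(fit$sigma)),
    lapply(split(seq_len(nrow(d)), d$subject), function(i) X[i, , drop = FALSE]),
    split(d$y, d$subject), gauss_hermite(1))
  expect_gt(abs(ll1_at_10 - ref_ll), abs(fit$logLik - ref_ll))
  expect_gt(abs(fit1$logLik - fit$logLik), 1e-8)
})

test_that("the built-in fitter agrees with lme4 at nAGQ = 10", {
  d <- simulate_glmm_frame(24, 50, sigma = 0.4, seed = 23)
  f_agq <- agq_logit(y ~ theta * age + alpha * age + (1 | subject), d, nAGQ = 10)
  f_l4 <- agq_logit(y ~ theta * age + alpha * age + (1 | subject), d,
                    nAGQ = 10, engine = "lme4")
  expect_lt(max(abs(coef(f_agq) - coef(f_l4))), 1e-2)
  expect_lt(abs(f_agq$sigma - f_l4$sigma), 1e-2)
  expect_lt(abs(f_agq$logLik - f_l4$logLik), 1e-3)
  expect_lt(max(abs(f_agq$se - f_l4$se)), 1e-2)
})

test_that("estimates are invariant to row order and subject relabeling", {
  d <- simulate_glmm_frame(12, 30, sigma = 0.5, seed = 24)
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 7)
  d2 <- d[sample(nrow(d)), ]
  d2$subject <- factor(paste0("relabeled_", d2$subject))
  fit2 <- agq_logit(y ~ theta + alpha + (1 | subject), d2, nAGQ = 7)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-6)
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-8)
})

test_that("Wald columns and information criteria are internally consistent", {
  d <- simulate_glmm_frame(10, 30, sigma = 0.4, seed = 25)
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
  s <- summary(fit)$coefficients
  expect_equal(s[, "z value"], s[, "Estimate"] / s[, "Std. Error"])
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$df)
  expect_equal(fit$BIC, -2 * fit$logLik + log(fit$n) * fit$df)
  expect_equal(AIC(fit), fit$AIC)
})

test_that("likelihood-ratio tests behave on identical and nested models", {
  d <- simulate_glmm_frame(12, 40, sigma = 0.4, seed = 26)
  full <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
  same <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
  out <- lrt(full, same)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  red <- agq_logit(y ~ 1 + (1 | subject), d, nAGQ = 5)
  out2 <- lrt(full, red)
  expect_gte(out2$chi2, 0)
  expect_equal(out2$chi2, 2 * (full$logLik - red$logLik))
  expect_equal(out2$df, 2)
  expect_equal(lrt(full, red), anova(red, full))
})

test_that("conditional R2 follows the latent-scale formula", {
  # fixed-effect variance 0 and random variance pi^2/3 -> exactly 0.5
  fake <- structure(list(X = matrix(1, 50, 1), coefficients = c(0),
                         sigma = pi / sqrt(3)), class = "agq_logit")
  expect_equal(conditional_r2(fake), 0.5)
  fake0 <- structure(list(X = matrix(1, 50, 1), coefficients = c(0), sigma = 0),
                     class = "agq_logit")
  expect_equal(conditional_r2(fake0), 0)
  # recomputation oracle on a real fit
  d <- simulate_glmm_frame(10, 30, sigma = 0.5, seed = 27)
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
  vf <- var(drop(fit$X %*% coef(fit)))
  expect_equal(conditional_r2(fit),
               (vf + fit$sigma^2) / (vf + fit$sigma^2 + pi^2 / 3))
})

test_that("model frames implement the two outcome contrasts", {
  tab <- data.frame(
    subject = rep(c("s1", "s2"), each = 15),
    age_group = rep(c("younger", "older"), each = 15),
    outcome = rep(c("miss", "item_only", "pair"), 10),
    theta = rnorm(30), alpha = rnorm(30)
  )
  fr <- build_frames(tab)
  expect_equal(nrow(fr$item_only), 20)
  expect_equal(nrow(fr$pair), 20)
  expect_equal(sort(unique(fr$item_only$y)), c(0, 1))
  # 10 miss + 10 item_only rows: the 10 pair trials never enter this frame
  expect_equal(sum(fr$item_only$y), 10)  # item_only coded 1 vs miss 0
  expect_equal(sum(fr$pair$y), 10)
  expect_equal(levels(fr$pair$age), c("younger", "older"))
  all_miss <- tab[tab$outcome == "miss", ]
  expect_error(build_frames(all_miss), "empty model frame")
})

test_that("prediction, simulation and residual methods are coherent", {
  d <- simulate_glmm_frame(8, 25, sigma = 0.4, seed = 28)
  fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
  pr <- predict(fit, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(stats::plogis(predict(fit, type = "link")), pr)
  expect_equal(residuals(fit, type = "response"), d$y - fit$fitted)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_identical(simulate(fit, nsim = 2, seed = 9), simulate(fit, nsim = 2, seed = 9))
})

test_that("parameter recovery at moderate size stays within sampling error", {
  truth <- c(0.5, 0.3, -0.5, -0.4, 0, 0.3)
  d <- simulate_glmm_frame(40, 60, beta = truth, sigma = 0.3, seed = 29)
  fit <- agq_logit(y ~ theta * age + alpha * age + (1 | subject), d, nAGQ = 10)
  expect_true(all(abs(coef(fit) - truth) < 3 * fit$se))
})
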