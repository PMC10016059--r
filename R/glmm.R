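#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for the weight function `exp(-z^2)` via the
#' Golub-Welsch eigenvalue decomposition of the Jacobi matrix.
#'
#' @param n Number of nodes (>= 1).
#' @return List with `nodes` (ascending) and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' @noRd
parse_ri_formula <- function(formula) {
  f_str <- paste(deparse(formula), collapse = " ")
  m <- regmatches(f_str, regexec("\\(\\s*1\\s*\\|\\s*([^)]+)\\)", f_str))[[1]]
  if (length(m) < 2)
    stop("formula must contain a random-intercept term (1 | group)")
  group <- trimws(m[2])
  fixed_str <- gsub("\\+?\\s*\\(\\s*1\\s*\\|[^)]+\\)", "", f_str)
  fixed_str <- sub("~\\s*$", "~ 1", trimws(fixed_str))
  list(fixed = stats::as.formula(fixed_str, env = environment(formula)),
       group = group)
}

# negative marginal log-likelihood by adaptive Gauss-Hermite quadrature
#' @noRd
agq_nll <- function(par, Xs, ys, gh) {
  p <- ncol(Xs[[1]])
  beta <- par[seq_len(p)]
  # clamp sigma away from 0/Inf so the mode search stays well defined
  sigma <- min(max(exp(par[p + 1L]), 1e-8), 1e8)
  inv_s2 <- 1 / sigma^2
  total <- 0
  for (i in seq_along(Xs)) {
    eta0 <- drop(Xs[[i]] %*% beta)
    y <- ys[[i]]
    # per-subject posterior mode of the random intercept (Newton)
    b <- 0
    for (it in 1:50) {
      mu <- stats::plogis(eta0 + b)
      g <- sum(y - mu) - b * inv_s2
      hh <- -(sum(mu * (1 - mu)) + inv_s2)
      step <- g / hh
      if (!is.finite(step)) break
      b <- b - step
      if (abs(step) < 1e-11) break
    }
    mu <- stats::plogis(eta0 + b)
    curv <- sum(mu * (1 - mu)) + inv_s2
    scale_b <- sqrt(2 / curv)
    bk <- b + scale_b * gh$nodes
    hk <- vapply(bk, function(bb) {
      eta <- eta0 + bb
      sum(y * eta - log1p(exp(eta))) - bb^2 * inv_s2 / 2
    }, numeric(1))
    lg <- log(gh$weights) + gh$nodes^2 + hk
    mlg <- max(lg)
    total <- total + mlg + log(sum(exp(lg - mlg))) + 0.5 * log(2 / curv) -
      log(sigma) - 0.5 * log(2 * pi)
  }
  -total
}

#' Random-intercept logistic regression by adaptive Gauss-Hermite quadrature
#'
#' Fits the mixed-effects logistic model `y ~ fixed effects + (1 | group)`
#' by maximum likelihood, integrating the per-group random intercept out of
#' the likelihood with adaptive Gauss-Hermite quadrature: each group's
#' integrand is re-centered at its posterior mode and scaled by the local
#' curvature before applying the `nAGQ`-node rule, so `nAGQ = 1` is the
#' Laplace approximation.  Optimization is quasi-Newton (BFGS) on
#' `(beta, log sigma)` from fixed starting values (zeros; sigma = 1), making
#' the fit deterministic given the data.  Wald standard errors come from
#' the numerically differentiated observed information at the optimum.
#'
#' @param formula Model formula including a `(1 | group)` term, e.g.
#'   `y ~ theta * age + alpha * age + (1 | subject)`.
#' @param data Data frame containing the response (0/1, logical or 2-level
#'   factor), predictors and grouping column.
#' @param nAGQ Number of quadrature nodes (default 10).
#' @param engine `"agq"` for the built-in fitter or `"lme4"` to delegate to
#'   `lme4::glmer` (same `nAGQ`) behind the identical interface, used for
#'   cross-validation of the fitter.
#' @param reltol Relative convergence tolerance on the deviance.
#' @return Object of class `"agq_logit"` with components `coefficients`,
#'   `se`, `sigma` (random-intercept sd), `logLik`, `deviance`, `vcov`,
#'   `ranef` (posterior modes), `fitted`, and bookkeeping fields.
#' @seealso [lrt()], [conditional_r2()], and the `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `simulate`, `residuals` and `anova`
#'   methods.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_glmm_frame(n_subjects = 12, n_trials = 30,
#'                          beta = c(0.3, 0.4, -0.5), sigma = 0.5)
#' fit <- agq_logit(y ~ theta + alpha + (1 | subject), d, nAGQ = 5)
#' coef(fit)
agq_logit <- function(formula, data, nAGQ = 10L, engine = c("agq", "lme4"),
                      reltol = 1e-10) {
  engine <- match.arg(engine)
  pf <- parse_ri_formula(formula)
  if (!pf$group %in% names(data)) stop("grouping column '", pf$group, "' not in data")
  mf <- stats::model.frame(pf$fixed, data = data, na.action = stats::na.omit)
  if (nrow(mf) == 0L) stop("empty model frame")
  omitted <- attr(mf, "na.action")
  keep <- if (is.null(omitted)) seq_len(nrow(data)) else setdiff(seq_len(nrow(data)), omitted)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design matrix is rank deficient")
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary")
  grp <- factor(data[[pf$group]][keep])
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  if (engine == "lme4") return(agq_logit_lme4(formula, data, nAGQ, pf, X, y, grp))

  idx <- split(seq_along(y), grp)
  Xs <- lapply(idx, function(i) X[i, , drop = FALSE])
  ys <- lapply(idx, function(i) y[i])
  gh <- gauss_hermite(nAGQ)
  p <- ncol(X)
  start <- c(rep(0, p), 0)
  opt <- stats::optim(start, agq_nll, Xs = Xs, ys = ys, gh = gh,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = reltol))
  if (opt$convergence != 0)
    warning("optimizer did not report convergence (code ", opt$convergence, ")")
  par <- opt$par
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- min(max(exp(par[p + 1L]), 1e-8), 1e8)
  if (max(abs(beta)) > 30)
    warning("extreme coefficient magnitudes; possible complete separation")
  H <- stats::optimHess(par, agq_nll, Xs = Xs, ys = ys, gh = gh)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V)[seq_len(p)])) ||
      any(diag(V)[seq_len(p)] < 0)) {
    # fall back to the fixed-effects block when the sigma direction is flat
    V <- matrix(NA_real_, p + 1L, p + 1L)
    Vb <- tryCatch(solve(H[seq_len(p), seq_len(p), drop = FALSE]),
                   error = function(e) matrix(NA_real_, p, p))
    V[seq_len(p), seq_len(p)] <- Vb
  }
  se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
  names(se) <- colnames(X)
  ll <- -opt$value

  # conditional modes for prediction/residuals
  inv_s2 <- 1 / sigma^2
  ranef <- vapply(seq_along(Xs), function(i) {
    eta0 <- drop(Xs[[i]] %*% beta); b <- 0
    for (it in 1:50) {
      mu <- stats::plogis(eta0 + b)
      step <- (sum(ys[[i]] - mu) - b * inv_s2) /
        (-(sum(mu * (1 - mu)) + inv_s2))
      if (!is.finite(step)) break
      b <- b - step
      if (abs(step) < 1e-11) break
    }
    b
  }, numeric(1))
  names(ranef) <- names(Xs)
  eta <- drop(X %*% beta) + ranef[as.character(grp)]
  k <- p + 1L
  structure(
    list(coefficients = beta, se = se, sigma = sigma, vcov = V,
         logLik = ll, deviance = -2 * ll, df = k,
         AIC = -2 * ll + 2 * k, BIC = -2 * ll + log(length(y)) * k,
         nAGQ = nAGQ, engine = "agq", formula = formula, fixed = pf$fixed,
         group = pf$group, X = X, y = y, grp = grp, ranef = ranef,
         fitted = stats::plogis(eta), n = length(y), n_groups = nlevels(grp),
         convergence = opt$convergence),
    class = "agq_logit"
  )
}

# delegate to lme4::glmer, reshaped into the same object contract
#' @noRd
agq_logit_lme4 <- function(formula, data, nAGQ, pf, X, y, grp) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("engine = 'lme4' requires the lme4 package")
  dat <- data
  fit <- lme4::glmer(formula, data = dat, family = stats::binomial(),
                     nAGQ = nAGQ)
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  sigma <- sqrt(as.numeric(lme4::VarCorr(fit)[[pf$group]]))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta) + 1L
  re <- lme4::ranef(fit)[[pf$group]][, 1]
  names(re) <- rownames(lme4::ranef(fit)[[pf$group]])
  structure(
    list(coefficients = beta, se = se, sigma = sigma,
         vcov = as.matrix(stats::vcov(fit)),
         logLik = ll, deviance = -2 * ll, df = k,
         AIC = -2 * ll + 2 * k, BIC = -2 * ll + log(length(y)) * k,
         nAGQ = nAGQ, engine = "lme4", formula = formula, fixed = pf$fixed,
         group = pf$group, X = X, y = y, grp = grp, ranef = re,
         fitted = stats::fitted(fit), n = length(y), n_groups = nlevels(grp),
         convergence = 0L, lme4_fit = fit),
    class = "agq_logit"
  )
}

#' @export
print.agq_logit <- function(x, ...) {
  cat("Random-intercept logistic model (", x$engine, ", nAGQ = ", x$nAGQ,
      ")\n", sep = "")
  cat(deparse(x$formula), "\n")
  cat(sprintf("  %d obs, %d groups; sigma = %.3f; logLik = %.1f\n",
              x$n, x$n_groups, x$sigma, x$logLik))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.agq_logit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma = object$sigma,
              logLik = object$logLik, AIC = object$AIC, BIC = object$BIC,
              r2 = conditional_r2(object), n = object$n,
              n_groups = object$n_groups, formula = object$formula,
              nAGQ = object$nAGQ, engine = object$engine)
  class(out) <- "summary.agq_logit"
  out
}

#' @export
print.summary.agq_logit <- function(x, ...) {
  cat(deparse(x$formula), "\n")
  cat(sprintf("%d obs, %d groups; random-intercept sd %.3f (nAGQ = %d, %s)\n",
              x$n, x$n_groups, x$sigma, x$nAGQ, x$engine))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("logLik %.1f  AIC %.1f  BIC %.1f  conditional R2 %.3f\n",
              x$logLik, x$AIC, x$BIC, x$r2))
  invisible(x)
}

#' @export
coef.agq_logit <- function(object, ...) object$coefficients

#' @export
vcov.agq_logit <- function(object, ...) {
  p <- length(object$coefficients)
  object$vcov[seq_len(p), seq_len(p), drop = FALSE]
}

#' @export
logLik.agq_logit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
nobs.agq_logit <- function(object, ...) object$n

#' @export
predict.agq_logit <- function(object, newdata = NULL,
                              type = c("link", "response"),
                              random = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    g <- as.character(object$grp)
  } else {
    X <- stats::model.matrix(stats::delete.response(stats::terms(object$fixed)),
                             newdata)
    g <- as.character(newdata[[object$group]])
  }
  eta <- drop(X %*% object$coefficients)
  if (random) {
    b <- object$ranef[g]
    b[is.na(b)] <- 0  # unseen groups get the population intercept
    eta <- eta + unname(b)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.agq_logit <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  mu <- object$fitted
  y <- object$y
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
}

#' @export
simulate.agq_logit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    eta_fix <- drop(object$X %*% object$coefficients)
    g <- as.integer(object$grp)
    out <- replicate(nsim, {
      b <- stats::rnorm(object$n_groups, 0, object$sigma)
      stats::rbinom(object$n, 1, stats::plogis(eta_fix + b[g]))
    })
    as.data.frame(out)
  })
}

#' @export
anova.agq_logit <- function(object, ..., test = "LRT") {
  fits <- list(object, ...)
  if (length(fits) < 2L) stop("supply two nested fits to compare")
  fits <- fits[order(vapply(fits, function(f) f$df, numeric(1)))]
  lrt(fits[[2]], fits[[1]])
}

#' Likelihood-ratio test between nested random-intercept logistic fits
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` with degrees of freedom equal
#' to the difference in parameter count; p-value from the upper chi-square
#' tail.  Both models must be fitted to the same observations.
#'
#' @param full,reduced `"agq_logit"` fits, reduced nested in full.
#' @param df Optional explicit degrees of freedom (defaults to the
#'   parameter-count difference).
#' @return List with `chi2`, `df`, `p`, `logLik_full`, `logLik_reduced`.
#' @export
lrt <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "agq_logit"), inherits(reduced, "agq_logit"))
  if (full$n != reduced$n)
    stop("models were fitted to different numbers of observations")
  if (is.null(df)) df <- full$df - reduced$df
  if (df < 0) stop("'full' has fewer parameters than 'reduced'")
  chi2 <- 2 * (full$logLik - reduced$logLik)
  if (chi2 < 0) {
    if (chi2 < -1e-6) warning("negative LRT statistic (", format(chi2),
                              "); models may not be nested")
    chi2 <- 0
  }
  p <- if (df == 0) as.numeric(chi2 == 0) else stats::pchisq(chi2, df, lower.tail = FALSE)
  if (df == 0 && chi2 == 0) p <- 1
  list(chi2 = chi2, df = df, p = p,
       logLik_full = full$logLik, logLik_reduced = reduced$logLik)
}

#' Conditional R-squared of a random-intercept logistic model
#'
#' Latent-scale variance decomposition for logit models: the variance of
#' the fixed-effect linear predictor plus the random-intercept variance,
#' divided by the same sum plus the logistic distribution variance
#' `pi^2 / 3`.
#'
#' @param fit An `"agq_logit"` object.
#' @return Proportion in `[0, 1)`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "agq_logit"))
  vf <- stats::var(drop(fit$X %*% fit$coefficients))
  (vf + fit$sigma^2) / (vf + fit$sigma^2 + pi^2 / 3)
}

#' Build the item-only and pair model frames from a trial table
#'
#' The item-only model contrasts misses (0) against item-only memory (1);
#' the pair model contrasts item-only (0) against pair memory (1).  Age is
#' a factor with younger as the reference level.
#'
#' @param table Trial table (see [make_trial_table()] /
#'   [simulate_trial_table()]).
#' @return List with data frames `item_only` and `pair` (columns y, theta,
#'   alpha, age, subject).
#' @export
build_frames <- function(table) {
  stopifnot(all(c("subject", "age_group", "outcome", "theta", "alpha") %in% names(table)))
  mk <- function(drop_outcome, one_outcome) {
    d <- table[table$outcome != drop_outcome, ]
    if (nrow(d) == 0L) stop("empty model frame after dropping ", drop_outcome)
    data.frame(y = as.integer(d$outcome == one_outcome),
               theta = d$theta, alpha = d$alpha,
               age = factor(d$age_group, levels = c("younger", "older")),
               subject = factor(d$subject),
               stringsAsFactors = FALSE)
  }
  list(item_only = mk("pair", "item_only"), pair = mk("miss", "pair"))
}

#' Fit the two single-trial retrieval-outcome models
#'
#' Fits `y ~ theta * age + alpha * age + (1 | subject)` for the item-only
#' and the pair contrast, together with the two reduced comparisons used to
#' validate the models: the same model without the EEG predictors
#' (likelihood-ratio df 4) and the intercept-plus-random-intercept-only
#' model (df 5).
#'
#' @param table Trial table with subject, age_group, outcome, theta, alpha.
#' @param nAGQ Quadrature nodes (default 10).
#' @param engine Fitting engine, see [agq_logit()].
#' @return List of class `"sme_glmm"`: for each contrast, `fit`, `lrt_eeg`,
#'   `lrt_null` and `r2`.
#' @export
fit_outcome_models <- function(table, nAGQ = 10L, engine = "agq") {
  frames <- build_frames(table)
  out <- lapply(frames, function(fr) {
    full <- agq_logit(y ~ theta * age + alpha * age + (1 | subject), fr,
                      nAGQ = nAGQ, engine = engine)
    no_eeg <- agq_logit(y ~ age + (1 | subject), fr, nAGQ = nAGQ, engine = engine)
    null <- agq_logit(y ~ 1 + (1 | subject), fr, nAGQ = nAGQ, engine = engine)
    list(fit = full,
         lrt_eeg = lrt(full, no_eeg),
         lrt_null = lrt(full, null),
         r2 = conditional_r2(full))
  })
  structure(out, class = "sme_glmm")
}

#' @export
print.sme_glmm <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "model ==\n")
    print(summary(x[[nm]]$fit))
    cat(sprintf("  LRT vs no-EEG: chi2(%d) = %.2f, p = %.3g\n",
                x[[nm]]$lrt_eeg$df, x[[nm]]$lrt_eeg$chi2, x[[nm]]$lrt_eeg$p))
    cat(sprintf("  LRT vs intercept-only: chi2(%d) = %.2f, p = %.3g\n",
                x[[nm]]$lrt_null$df, x[[nm]]$lrt_null$chi2, x[[nm]]$lrt_null$p))
  }
  invisible(x)
}

#' Simulate a model frame from the random-intercept logistic model
#'
#' Draws standard-normal theta and alpha predictors, a balanced younger /
#' older factor across subjects, subject intercepts `N(0, sigma)` and
#' Bernoulli outcomes from the linear predictor `X beta` — the generative
#' model the fitter assumes, used for parameter-recovery checks.
#'
#' @param n_subjects Number of subjects (split evenly across age groups).
#' @param n_trials Trials per subject.
#' @param beta Fixed-effect vector, matched by position to the columns of
#'   `model.matrix(~ theta * age + alpha * age)` truncated to
#'   `length(beta)`; shorter vectors use the leading columns.
#' @param sigma Random-intercept standard deviation.
#' @param seed Optional integer seed.
#' @return Data frame with y, theta, alpha, age, subject.
#' @export
simulate_glmm_frame <- function(n_subjects, n_trials,
                                beta = c(0.5, 0.06, -0.43, -0.36, -0.01, 0.30),
                                sigma = 0.3, seed = NULL) {
  with_seed(seed, {
    subject <- factor(rep(sprintf("s%03d", seq_len(n_subjects)), each = n_trials))
    age <- factor(rep(rep(c("younger", "older"), length.out = n_subjects),
                      each = n_trials), levels = c("younger", "older"))
    d <- data.frame(
      theta = stats::rnorm(n_subjects * n_trials),
      alpha = stats::rnorm(n_subjects * n_trials),
      age = age, subject = subject
    )
    X <- stats::model.matrix(~ theta * age + alpha * age, d)
    X <- X[, seq_along(beta), drop = FALSE]
    b <- stats::rnorm(n_subjects, 0, sigma)
    eta <- drop(X %*% beta) + b[as.integer(subject)]
    d$y <- stats::rbinom(nrow(d), 1, stats::plogis(eta))
    d
  })
}
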