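# ---- fixture builders ------------------------------------------------------

# minimal tfr_set from a trials x channels x freqs x times power array
make_tfr <- function(pow, times = NULL, freqs = NULL, events = NULL,
                     mask = NULL) {
  d <- dim(pow)
  if (is.null(times)) times <- seq(-0.7, by = 0.05, length.out = d[4])
  if (is.null(freqs)) freqs <- seq(2, by = 2, length.out = d[3])
  channels <- sprintf("ch%02d", seq_len(d[2]))
  dimnames(pow) <- list(NULL, channels, NULL, NULL)
  if (is.null(mask)) mask <- matrix(TRUE, d[3], d[4])
  if (is.null(events))
    events <- data.frame(subject = "s1", age_group = "younger",
                         trial = seq_len(d[1]), condition = "match",
                         outcome = rep_len(c("miss", "item_only", "pair"), d[1]),
                         stringsAsFactors = FALSE)
  structure(list(power = pow, times = times, freqs = freqs,
                 channels = channels, mask = mask, events = events),
            class = "tfr_set")
}

# minimal epoch_set from a trials x channels x samples array
make_epochs <- function(dat, sfreq = 100, t0 = -2) {
  d <- dim(dat)
  channels <- sprintf("ch%02d", seq_len(d[2]))
  dimnames(dat) <- list(NULL, channels, NULL)
  structure(list(
    data = dat, times = seq(t0, by = 1 / sfreq, length.out = d[3]),
    sfreq = sfreq, channels = channels,
    events = data.frame(subject = "s1", age_group = "younger",
                        trial = seq_len(d[1]), condition = "match",
                        outcome = "pair", stringsAsFactors = FALSE)),
    class = "epoch_set")
}

# fully connected chain graph over n generic channels ch01..chNN
chain_graph <- function(n) {
  chs <- sprintf("ch%02d", seq_len(n))
  adj <- lapply(seq_len(n), function(i)
    chs[setdiff(c(i - 1, i + 1), c(0, n + 1))])
  names(adj) <- chs
  adj
}

# ---- independent oracles ---------------------------------------------------

# exhaustive connected-component labelling on a channel x freq x time mask,
# same connectivity contract as the package but via plain BFS over an edge
# list built by brute force
ref_components <- function(mask, adj_idx, minnbchan = 0) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (minnbchan > 0 && nrow(pts) > 0) {
    keep <- vapply(seq_len(nrow(pts)), function(i) {
      p <- pts[i, ]
      nb <- adj_idx[[p[1]]]
      sum(mask[cbind(nb, p[2], p[3])]) >= minnbchan
    }, logical(1))
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n == 0) return(list())
  connected <- function(a, b) {
    (a[1] == b[1] && ((abs(a[2] - b[2]) == 1 && a[3] == b[3]) ||
                      (a[2] == b[2] && abs(a[3] - b[3]) == 1))) ||
      (a[2] == b[2] && a[3] == b[3] && b[1] %in% adj_idx[[a[1]]])
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (!comp[j] && connected(pts[i, ], pts[j, ])) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lapply(seq_len(cur), function(k) pts[comp == k, , drop = FALSE])
}

# two-sided periodogram PSD estimate of one signal (units: var / Hz-bin scale
# matching the wavelet power convention, i.e. |X|^2 / (N * sfreq))
periodogram_psd <- function(x, sfreq) {
  n <- length(x)
  Mod(stats::fft(x))^2 / (n * sfreq)
}

# mean periodogram PSD within [f1, f2] averaged over rows of a trials x
# samples matrix
band_psd <- function(xm, sfreq, f1, f2) {
  n <- ncol(xm)
  fax <- (seq_len(n) - 1) * sfreq / n
  sel <- fax >= f1 & fax <= f2
  mean(apply(xm, 1, function(x) mean(periodogram_psd(x, sfreq)[sel])))
}

# textbook mixed-design ANOVA sums of squares (between: age; within: level)
ref_mixed_anova <- function(rates) {
  y <- as.matrix(rates[, c("miss", "item_only", "pair")])
  g <- factor(rates$age_group)
  n <- nrow(y); a <- nlevels(g); k <- ncol(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  group_means <- tapply(subj_means, g, mean)
  level_means <- colMeans(y)
  cell_means <- apply(y, 2, function(col) tapply(col, g, mean))  # a x k
  ng <- as.vector(table(g))
  ss_age <- k * sum(ng * (group_means - grand)^2)
  ss_subj_within <- k * sum((subj_means - group_means[as.integer(g)])^2)
  ss_level <- n * sum((level_means - grand)^2)
  ss_cells <- sum(ng * (t(cell_means) - grand)^2)
  ss_interaction <- ss_cells - ss_age - ss_level
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_age - ss_subj_within - ss_level - ss_interaction
  df_age <- a - 1; df_s <- n - a; df_level <- k - 1
  df_int <- (a - 1) * (k - 1); df_res <- (k - 1) * (n - a)
  data.frame(
    effect = c("age", "memory_level", "age:memory_level"),
    df1 = c(df_age, df_level, df_int),
    df2 = c(df_s, df_res, df_res),
    F = c((ss_age / df_age) / (ss_subj_within / df_s),
          (ss_level / df_level) / (ss_resid / df_res),
          (ss_interaction / df_int) / (ss_resid / df_res))
  )
}

# marginal log-likelihood of a random-intercept logistic model by dense
# trapezoid integration over the random effect (independent of the AGQ path)
ref_marginal_loglik <- function(beta, sigma, X, y, grp, half_width = 10,
                                n_grid = 20001) {
  eta0 <- drop(X %*% beta)
  total <- 0
  for (g in levels(grp)) {
    i <- grp == g
    b <- seq(-half_width * sigma, half_width * sigma, length.out = n_grid)
    lp <- vapply(b, function(bb) {
      eta <- eta0[i] + bb
      sum(y[i] * eta - log1p(exp(eta))) + stats::dnorm(bb, 0, sigma, log = TRUE)
    }, numeric(1))
    m <- max(lp)
    total <- total + m + log(sum(exp(lp - m)) * (b[2] - b[1]))
  }
  total
}
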