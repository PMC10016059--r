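mk_map <- function(vals, n_ch = 4, n_f = 3, n_t = 3) {
  array(vals, dim = c(n_ch, n_f, n_t),
        dimnames = list(sprintf("ch%02d", seq_len(n_ch)), NULL, NULL))
}

mk_tmaps <- function(N, n_ch = 4, n_f = 3, n_t = 3, effect = 0, noise = 1) {
  lapply(seq_len(N), function(i) {
    mk <- function(shift) array(rnorm(n_ch * n_f * n_t, shift, sd = noise),
                                dim = c(n_ch, n_f, n_t),
                                dimnames = list(sprintf("ch%02d", seq_len(n_ch)),
                                                NULL, NULL))
    list(miss = mk(0), item_only = mk(effect), pair = mk(2 * effect))
  })
}

complete_graph <- function(n) {
  chs <- sprintf("ch%02d", seq_len(n))
  adj <- lapply(seq_len(n), function(i) chs[-i])
  names(adj) <- chs
  adj
}

test_that("regression t matches direct arithmetic and a per-point lm oracle", {
  # three subjects whose slopes are exactly 1, 2, 3 at every point
  tmaps <- lapply(1:3, function(i)
    list(miss = mk_map(0), item_only = mk_map(i), pair = mk_map(2 * i)))
  tt <- depsamples_regression_t(tmaps)
  expect_equal(unname(tt[1, 1, 1]), 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(unname(tt[1, 1, 1]), 2 * sqrt(3), tolerance = 1e-12)
  # random data: per-point slopes via lm, then one-sample t
  set.seed(2)
  tmaps_r <- mk_tmaps(5)
  tt_r <- depsamples_regression_t(tmaps_r)
  codes <- c(1, 2, 3)
  for (ch in 1:4) for (fr in 1:3) for (k in 1:3) {
    slopes <- vapply(tmaps_r, function(s) {
      y <- c(s$miss[ch, fr, k], s$item_only[ch, fr, k], s$pair[ch, fr, k])
      unname(coef(lm(y ~ codes))[2])
    }, numeric(1))
    want <- mean(slopes) / (sd(slopes) / sqrt(5))
    expect_equal(unname(tt_r[ch, fr, k]), want, tolerance = 1e-10)
  }
  # all conditions identical -> zero statistic, guarded
  tmaps_f <- lapply(1:3, function(i) list(miss = mk_map(1), item_only = mk_map(1),
                                          pair = mk_map(1)))
  expect_true(all(depsamples_regression_t(tmaps_f) == 0))
})

test_that("cluster formation honors the spatial neighbor constraint", {
  graph <- complete_graph(4)
  # a single suprathreshold point cannot recruit 2 neighboring channels
  stat <- mk_map(0)
  stat[2, 2, 2] <- 5
  expect_length(find_clusters(stat, 3, graph), 0)
  # the same point suprathreshold on a channel and >= 2 of its neighbors at one
  # freq-time bin, plus an adjacent time bin -> one cluster with summed mass
  stat2 <- mk_map(0)
  stat2[1:3, 2, 2] <- 4
  stat2[1:3, 2, 3] <- 4
  cl <- find_clusters(stat2, 3, graph)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 24)
  expect_equal(nrow(cl[[1]]$members), 6)
  # fully suprathreshold map -> single cluster covering the grid
  stat3 <- mk_map(5)
  cl3 <- find_clusters(stat3, 3, graph)
  expect_length(cl3, 1)
  expect_equal(nrow(cl3[[1]]$members), length(stat3))
  expect_equal(cl3[[1]]$mass, sum(stat3))
})

test_that("component labelling agrees with an exhaustive reference search", {
  set.seed(4)
  graph <- chain_graph(5)
  adj_idx <- lapply(seq_len(5), function(i) setdiff(c(i - 1, i + 1), c(0, 6)))
  for (rep in 1:10) {
    stat <- array(rnorm(5 * 4 * 4), dim = c(5, 4, 4),
                  dimnames = list(names(graph), NULL, NULL))
    thr <- 0.8
    for (mnb in c(0, 2)) {
      cl <- find_clusters(stat, thr, graph, min_nb_chan = mnb)
      ref_pos <- ref_components(stat > thr, adj_idx, mnb)
      ref_neg <- ref_components(stat < -thr, adj_idx, mnb)
      expect_equal(length(cl), length(ref_pos) + length(ref_neg))
      got_masses <- sort(vapply(cl, `[[`, numeric(1), "mass"))
      ref_masses <- sort(c(vapply(ref_pos, function(m) sum(stat[m]), numeric(1)),
                           vapply(ref_neg, function(m) sum(stat[m]), numeric(1))))
      expect_equal(got_masses, ref_masses, tolerance = 1e-12)
    }
  }
})

test_that("permutation p-values hit the formula floor for overwhelming effects", {
  set.seed(6)
  tmaps <- mk_tmaps(8, effect = 5, noise = 0.5)
  res <- permutation_test(tmaps, chain_graph(4),
                          cluster_config(n_perm = 99, min_nb_chan = 1,
                                         exact = FALSE, seed = 1))
  top <- res$clusters[[1]]
  expect_equal(top$p, 1 / 100)
  expect_true(top$significant)
})

test_that("negating the data swaps cluster signs with identical masses", {
  set.seed(7)
  tmaps <- mk_tmaps(6, effect = 1.5)
  neg <- lapply(tmaps, function(s) lapply(s, function(a) -a))
  cfg <- cluster_config(n_perm = 200, min_nb_chan = 1, exact = FALSE, seed = 3)
  r1 <- permutation_test(tmaps, chain_graph(4), cfg)
  r2 <- permutation_test(neg, chain_graph(4), cfg)
  m1 <- sort(vapply(r1$clusters, `[[`, numeric(1), "mass"))
  m2 <- sort(-vapply(r2$clusters, `[[`, numeric(1), "mass"))
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(r1$stat, -r2$stat, tolerance = 1e-12)
})

test_that("permutation p is invariant to channel relabeling", {
  set.seed(8)
  tmaps <- mk_tmaps(6, effect = 1.2)
  perm <- c(3, 1, 4, 2)
  graph <- chain_graph(4)
  relabel <- function(a) {
    out <- a[perm, , , drop = FALSE]
    dimnames(out)[[1]] <- dimnames(a)[[1]][perm]
    out
  }
  tmaps_r <- lapply(tmaps, function(s) lapply(s, relabel))
  cfg <- cluster_config(n_perm = 150, min_nb_chan = 1, exact = FALSE, seed = 5)
  r1 <- permutation_test(tmaps, graph, cfg)
  r2 <- permutation_test(tmaps_r, graph, cfg)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "p"),
               vapply(r2$clusters, `[[`, numeric(1), "p"))
  expect_equal(sort(vapply(r1$clusters, `[[`, numeric(1), "mass")),
               sort(vapply(r2$clusters, `[[`, numeric(1), "mass")),
               tolerance = 1e-12)
})

test_that("tiny samples switch to exact enumeration of all relabelings", {
  set.seed(9)
  tmaps <- mk_tmaps(3, effect = 2)
  expect_message(
    res <- permutation_test(tmaps, chain_graph(4),
                            cluster_config(n_perm = 5000, min_nb_chan = 1,
                                           point_p = 0.1)),
    "enumerating"
  )
  expect_true(res$exact)
  expect_equal(res$n_perm, 6^3)
  expect_length(res$null_pos, 216)
})

test_that("stronger injected linear effects never shrink the top cluster mass", {
  masses <- vapply(c(0.5, 1.5, 3), function(eff) {
    set.seed(11)  # paired seeds: same noise, growing effect
    tmaps <- mk_tmaps(8, effect = eff)
    stat <- depsamples_regression_t(tmaps)
    cl <- find_clusters(stat, qt(0.995, 7), chain_graph(4), min_nb_chan = 1)
    if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})
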