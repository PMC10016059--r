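#' Cluster-based permutation test settings
#'
#' @param point_p Two-sided p-value threshold for a point to enter a cluster
#'   (default 0.01); converted to a t cutoff via the Student quantile with
#'   `df = N - 1` subjects.
#' @param min_nb_chan Minimum number of suprathreshold neighboring channels a
#'   point needs (at its frequency-time bin) to enter a cluster (default 2).
#' @param n_perm Number of Monte Carlo permutations (default 5000).
#' @param cluster_alpha Per-tail significance threshold for cluster p-values
#'   (default 0.025, i.e. two-sided 0.05).
#' @param codes Named numeric condition codes for the linear contrast
#'   (default miss = 1, item_only = 2, pair = 3).
#' @param exact `NULL` (auto: enumerate exhaustively when the number of
#'   distinct within-subject relabelings does not exceed `n_perm`), `TRUE`
#'   or `FALSE`.
#' @param seed Optional integer seed for the permutation draws.
#' @return List of class `"cluster_config"`.
#' @export
cluster_config <- function(point_p = 0.01, min_nb_chan = 2L, n_perm = 5000L,
                           cluster_alpha = 0.025,
                           codes = c(miss = 1, item_only = 2, pair = 3),
                           exact = NULL, seed = NULL) {
  stopifnot(point_p > 0, point_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            n_perm >= 1, length(codes) == 3, !is.null(names(codes)))
  structure(list(point_p = point_p, min_nb_chan = as.integer(min_nb_chan),
                 n_perm = as.integer(n_perm), cluster_alpha = cluster_alpha,
                 codes = codes, exact = exact, seed = seed),
            class = "cluster_config")
}

# stack per-subject tmap lists into Y[subject, condition, point]
#' @noRd
stack_tmaps <- function(tmaps, codes) {
  stopifnot(is.list(tmaps), length(tmaps) >= 2)
  cond_names <- names(codes)
  first <- tmaps[[1]]
  if (inherits(first, "tmap") || !is.list(first))
    stop("tmaps must be a list of subjects, each a named list of per-condition maps")
  get_arr <- function(x) if (inherits(x, "tmap")) x$t else x
  proto <- get_arr(first[[cond_names[1]]])
  dims <- dim(proto)
  P <- prod(dims)
  N <- length(tmaps)
  Y <- array(NA_real_, dim = c(N, 3, P))
  for (i in seq_len(N)) {
    for (k in seq_along(cond_names)) {
      a <- get_arr(tmaps[[i]][[cond_names[k]]])
      if (is.null(a)) stop("subject ", i, " lacks condition ", cond_names[k])
      if (!identical(dim(a), dims)) stop("inconsistent map dimensions")
      Y[i, k, ] <- a
    }
  }
  meta <- if (inherits(first[[cond_names[1]]], "tmap")) first[[cond_names[1]]] else NULL
  list(Y = Y, dims = dims, N = N,
       channels = if (!is.null(meta)) meta$channels else dimnames(proto)[[1]],
       freqs = if (!is.null(meta)) meta$freqs else NULL,
       times = if (!is.null(meta)) meta$times else NULL)
}

#' Dependent-samples linear regression t statistic
#'
#' For each channel x frequency x time point, fits each subject's
#' ordinary-least-squares slope of baseline-corrected power on the numeric
#' condition code, then computes the one-sample t of those slopes across
#' subjects (`mean slope / (sd of slopes / sqrt(N))`).  A positive statistic
#' indicates a linear power increase from miss to item-only to pair memory.
#'
#' @param tmaps List of subjects, each a named list of per-condition
#'   `"tmap"` objects (or plain arrays) with names matching `names(codes)`.
#' @param codes Named numeric condition codes.
#' @return Array of t statistics with the per-condition map dimensions.
#' @export
depsamples_regression_t <- function(tmaps, codes = c(miss = 1, item_only = 2, pair = 3)) {
  st <- stack_tmaps(tmaps, codes)
  w <- slope_weights(codes)
  slopes <- apply_weights(st$Y, w)          # N x P
  tt <- colmeans_t(slopes)
  out <- array(tt, dim = st$dims)
  if (!is.null(st$channels)) dimnames(out) <- list(st$channels, NULL, NULL)
  out
}

#' @noRd
slope_weights <- function(codes) {
  cc <- codes - mean(codes)
  cc / sum(cc^2)
}

#' @noRd
apply_weights <- function(Y, w) {
  Y[, 1, ] * w[1] + Y[, 2, ] * w[2] + Y[, 3, ] * w[3]
}

# one-sample t over rows of an N x P matrix; 0/0 guarded to 0
#' @noRd
colmeans_t <- function(slopes) {
  N <- nrow(slopes)
  m <- colMeans(slopes)
  v <- (colSums(slopes^2) - N * m^2) / (N - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / N)
  bad <- !is.finite(tt)
  if (any(bad)) {
    if (any(m[bad] != 0)) warning("non-finite regression t at points with zero slope variance")
    tt[bad] <- 0
  }
  tt
}

#' Find spectro-temporal clusters in a statistic map
#'
#' Thresholds the map at `+/- threshold`, applies the minimum-neighbor
#' spatial constraint, and labels connected components separately for the
#' positive and negative tails.  Connectivity is adjacency in frequency or
#' time within a channel, plus the sensor neighborhood graph within a
#' frequency-time bin.
#'
#' @param stat Channel x frequency x time statistic array.
#' @param threshold Positive t cutoff.
#' @param graph Neighborhood adjacency list (see [channel_neighbors()]);
#'   names must cover the map's channels.
#' @param channels Channel labels for the first array dimension (defaults to
#'   `dimnames(stat)[[1]]`).
#' @param min_nb_chan Minimum suprathreshold neighbor channels (default 2).
#' @return List of clusters sorted by decreasing `|mass|`; each has `sign`
#'   (+1/-1), `members` (matrix of channel/freq/time indices), `mass`.
#' @export
find_clusters <- function(stat, threshold, graph, channels = dimnames(stat)[[1]],
                          min_nb_chan = 2L) {
  stopifnot(length(dim(stat)) == 3, threshold > 0)
  if (length(graph) == 0L) stop("empty neighborhood graph")
  if (is.null(channels)) stop("channel labels are required")
  adj <- adjacency_index(graph, channels)
  out <- c(
    label_tail(stat > threshold, stat, adj, min_nb_chan, +1),
    label_tail(stat < -threshold, stat, adj, min_nb_chan, -1)
  )
  out[order(-abs(vapply(out, `[[`, numeric(1), "mass")))]
}

#' @noRd
adjacency_index <- function(graph, channels) {
  miss <- setdiff(channels, names(graph))
  if (length(miss))
    warning("channels absent from the neighborhood graph (treated as isolated): ",
            paste(miss, collapse = ", "))
  lapply(channels, function(ch) {
    if (ch %in% names(graph)) match(intersect(graph[[ch]], channels), channels) - 1L
    else integer(0)
  })
}

#' @noRd
label_tail <- function(mask, stat, adj, min_nb_chan, sign) {
  if (!any(mask)) return(list())
  labels <- label_clusters_cpp(as.logical(mask), dim(stat), adj,
                               as.integer(min_nb_chan))
  k <- max(labels)
  if (k == 0L) return(list())
  lapply(seq_len(k), function(lab) {
    idx <- which(labels == lab)
    list(sign = sign,
         members = arrayInd(idx, dim(stat)),
         mass = sum(stat[idx]))
  })
}

# max positive / min negative cluster mass of a map (0 when no cluster)
#' @noRd
extreme_masses <- function(stat, threshold, adj, min_nb_chan) {
  pos <- 0; neg <- 0
  if (any(stat > threshold)) {
    cl <- label_tail(stat > threshold, stat, adj, min_nb_chan, +1)
    if (length(cl)) pos <- max(vapply(cl, `[[`, numeric(1), "mass"))
  }
  if (any(stat < -threshold)) {
    cl <- label_tail(stat < -threshold, stat, adj, min_nb_chan, -1)
    if (length(cl)) neg <- min(vapply(cl, `[[`, numeric(1), "mass"))
  }
  c(pos = pos, neg = neg)
}

#' Group-level cluster-based Monte Carlo permutation test
#'
#' Runs the dependent-samples linear regression across memory outcomes at
#' every channel x frequency x time point, forms clusters in the observed
#' map, and assesses each cluster's summed-t mass against a null
#' distribution obtained by permuting the three condition labels
#' independently within each subject and recording the maximum (per tail)
#' cluster mass of every permutation.  Cluster p-values use the
#' `(exceedances + 1) / (n_perm + 1)` estimator; when the number of distinct
#' relabelings `6^N` does not exceed `n_perm` the test switches to exact
#' enumeration of all relabelings (with a message).
#'
#' @param tmaps List of subjects, each a named list of per-condition
#'   `"tmap"` objects or arrays (names matching `names(cfg$codes)`).
#' @param graph Sensor neighborhood adjacency list.
#' @param cfg A [cluster_config()].
#' @return Object of class `"cluster_result"`: `clusters` (each with sign,
#'   members, mass, p, significant, and channel/frequency/time extents when
#'   axis labels are available), `stat` (observed map), `threshold`,
#'   `null_pos`, `null_neg`, `n_perm`, `exact`, plus axis labels.
#' @export
permutation_test <- function(tmaps, graph, cfg = cluster_config()) {
  st <- stack_tmaps(tmaps, cfg$codes)
  N <- st$N
  if (N < 2L) stop("need at least 2 subjects")
  adj <- adjacency_index(graph, st$channels)
  w <- slope_weights(cfg$codes)
  df <- N - 1L
  threshold <- stats::qt(1 - cfg$point_p / 2, df)

  slopes_obs <- apply_weights(st$Y, w)
  stat <- array(colmeans_t(slopes_obs), dim = st$dims)
  clusters <- find_clusters(stat, threshold, graph, channels = st$channels,
                            min_nb_chan = cfg$min_nb_chan)

  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # slopes under each of the 6 within-subject label arrangements
  S <- array(NA_real_, dim = c(6, N, dim(slopes_obs)[2]))
  for (a in 1:6) {
    wa <- w[perms[a, ]]
    S[a, , ] <- st$Y[, 1, ] * wa[1] + st$Y[, 2, ] * wa[2] + st$Y[, 3, ] * wa[3]
  }
  Sm <- matrix(S, nrow = 6 * N)  # row (a-1)+6*(i-1)+1 ... column-major: [a, i]

  exact <- cfg$exact
  n_arrangements <- 6^N
  if (is.null(exact)) exact <- is.finite(n_arrangements) && n_arrangements <= cfg$n_perm
  if (length(clusters) == 0L) {
    null_pos <- numeric(0); null_neg <- numeric(0)
  } else if (exact) {
    message("enumerating all ", n_arrangements, " within-subject relabelings exactly")
    null_pos <- numeric(n_arrangements); null_neg <- numeric(n_arrangements)
    counter <- rep(1L, N)
    for (r in seq_len(n_arrangements)) {
      rows <- counter + 6L * (seq_len(N) - 1L)
      sl <- Sm[rows, , drop = FALSE]
      pstat <- array(colmeans_t(sl), dim = st$dims)
      ex <- extreme_masses(pstat, threshold, adj, cfg$min_nb_chan)
      null_pos[r] <- ex["pos"]; null_neg[r] <- ex["neg"]
      # increment mixed-radix counter
      for (i in seq_len(N)) {
        counter[i] <- counter[i] + 1L
        if (counter[i] <= 6L) break
        counter[i] <- 1L
      }
    }
  } else {
    null_pos <- numeric(cfg$n_perm); null_neg <- numeric(cfg$n_perm)
    with_seed(cfg$seed, {
      for (r in seq_len(cfg$n_perm)) {
        rows <- sample.int(6L, N, replace = TRUE) + 6L * (seq_len(N) - 1L)
        sl <- Sm[rows, , drop = FALSE]
        pstat <- array(colmeans_t(sl), dim = st$dims)
        ex <- extreme_masses(pstat, threshold, adj, cfg$min_nb_chan)
        null_pos[r] <- ex["pos"]; null_neg[r] <- ex["neg"]
      }
    })
  }

  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    if (cl$sign > 0) {
      exceed <- sum(null_pos >= cl$mass)
    } else {
      exceed <- sum(null_neg <= cl$mass)
    }
    cl$p <- if (exact) max(exceed, 1) / n_arrangements else (exceed + 1) / (cfg$n_perm + 1)
    cl$significant <- cl$p < cfg$cluster_alpha
    if (!is.null(st$channels)) cl$channels <- unique(st$channels[cl$members[, 1]])
    if (!is.null(st$freqs)) cl$freq_range <- range(st$freqs[cl$members[, 2]])
    if (!is.null(st$times)) cl$time_range <- range(st$times[cl$members[, 3]])
    clusters[[j]] <- cl
  }

  structure(
    list(clusters = clusters, stat = stat, threshold = threshold,
         null_pos = null_pos, null_neg = null_neg,
         n_perm = if (exact) n_arrangements else cfg$n_perm, exact = exact,
         channels = st$channels, freqs = st$freqs, times = st$times,
         cluster_alpha = cfg$cluster_alpha, n_subjects = N),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster-based permutation test:", x$n_subjects, "subjects,",
      x$n_perm, if (x$exact) "exact relabelings\n" else "permutations\n")
  cat(sprintf("  point threshold |t| > %.3f; cluster alpha %.3f per tail\n",
              x$threshold, x$cluster_alpha))
  if (length(x$clusters) == 0L) {
    cat("  no clusters\n")
    return(invisible(x))
  }
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %4d points, mass %9.1f, p = %.4f%s\n",
                if (cl$sign > 0) "positive" else "negative",
                nrow(cl$members), cl$mass, cl$p,
                if (isTRUE(cl$significant)) " *" else ""))
    if (!is.null(cl$freq_range))
      cat(sprintf("      %g-%g Hz, %.2f-%.2f s, %d channels\n",
                  cl$freq_range[1], cl$freq_range[2],
                  cl$time_range[1], cl$time_range[2], length(cl$channels)))
  }
  invisible(x)
}
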