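#' Build a frequency-and-region-of-interest mask from a significant cluster
#'
#' Selects the significant cluster of the requested sign with the largest
#' absolute mass and turns its member points into a binary channel x
#' frequency x time mask, optionally intersected with a frequency
#' restriction (e.g. limiting the positive cluster to the sustained 2-4 Hz
#' theta range).  The restriction can only remove points; emptying the mask
#' is an error.
#'
#' @param result A `"cluster_result"` from [permutation_test()].
#' @param sign `+1` for the positive (theta) cluster, `-1` for the negative
#'   (alpha/beta) cluster.
#' @param restriction Optional numeric length-2 Hz range, or `NULL`.
#' @param band Label stored with the mask (defaults to `"theta"` for
#'   positive, `"alphabeta"` for negative).
#' @return Object of class `"froi_mask"`: logical array `mask` plus `band`,
#'   `channels`, `freqs`, `times`.
#' @export
build_froi <- function(result, sign, restriction = NULL, band = NULL) {
  stopifnot(inherits(result, "cluster_result"), sign %in% c(-1, 1))
  cand <- Filter(function(cl) cl$sign == sign && isTRUE(cl$significant),
                 result$clusters)
  if (length(cand) == 0L)
    stop("no significant ", if (sign > 0) "positive" else "negative", " cluster")
  cl <- cand[[which.max(vapply(cand, function(x) abs(x$mass), numeric(1)))]]
  mask <- array(FALSE, dim = dim(result$stat))
  mask[cl$members] <- TRUE
  if (!is.null(restriction)) {
    stopifnot(length(restriction) == 2)
    if (is.null(result$freqs)) stop("cluster result carries no frequency axis")
    keep_f <- result$freqs >= restriction[1] & result$freqs <= restriction[2]
    mask[, !keep_f, ] <- FALSE
    if (!any(mask))
      stop("frequency restriction [", restriction[1], ", ", restriction[2],
           "] Hz leaves no cluster points")
  }
  if (is.null(band)) band <- if (sign > 0) "theta" else "alphabeta"
  structure(list(mask = mask, band = band, sign = sign,
                 channels = result$channels, freqs = result$freqs,
                 times = result$times),
            class = "froi_mask")
}

#' Average single-trial t-values within a FROI mask
#'
#' Unweighted mean over the mask's channel x frequency x time points for
#' each trial.  Points flagged invalid by the edge mask of the single-trial
#' container are excluded from the average (with a message reporting how
#' many).
#'
#' @param st A `"single_trial_t"` object.
#' @param froi A `"froi_mask"` (or a plain logical array of matching
#'   dimensions).
#' @return Numeric vector, one mean per trial.
#' @export
froi_extract <- function(st, froi) {
  stopifnot(inherits(st, "single_trial_t"))
  mask <- if (inherits(froi, "froi_mask")) froi$mask else froi
  stopifnot(identical(dim(mask), dim(st$t)[-1]))
  if (!any(mask)) stop("empty FROI mask")
  valid <- aperm(array(st$mask, dim = c(dim(st$mask), length(st$channels))),
                 c(3, 1, 2))
  n_bad <- sum(mask & !valid)
  if (n_bad > 0) {
    message(n_bad, " FROI points are edge-contaminated; excluded from the average")
    mask <- mask & valid
    if (!any(mask)) stop("all FROI points are edge-contaminated")
  }
  idx <- which(mask)
  n_tr <- dim(st$t)[1]
  flat <- matrix(st$t, nrow = n_tr)
  rowMeans(flat[, idx, drop = FALSE])
}

#' Standardize per-trial values within subject
#'
#' Subtracts each subject's mean and divides by the subject's (n-1) standard
#' deviation across that subject's trials, so every subject contributes
#' predictors with mean 0 and sd 1.
#'
#' @param values Numeric vector of per-trial values.
#' @param subjects Subject identifier per trial.
#' @return Numeric vector of the same length.
#' @export
zscore_within <- function(values, subjects) {
  stopifnot(length(values) == length(subjects))
  out <- numeric(length(values))
  for (s in unique(subjects)) {
    i <- subjects == s
    if (sum(i) < 2L) stop("subject ", s, " has fewer than 2 trials")
    sdv <- stats::sd(values[i])
    if (sdv == 0) stop("subject ", s, " has zero variance; cannot standardize")
    out[i] <- (values[i] - mean(values[i])) / sdv
  }
  out
}

#' Assemble and standardize the single-trial model frame
#'
#' Binds per-subject FROI means with the trial metadata and z-scores the
#' theta and alpha/beta predictors within subject.  Only categorized
#' match/mismatch trials (outcomes miss / item_only / pair) are retained.
#'
#' @param events Data frame with subject, age_group, trial, condition,
#'   outcome (stacked over subjects, same row order as the extracted values).
#' @param theta Per-trial theta FROI means (raw, t-value scale).
#' @param alpha Per-trial alpha/beta FROI means.
#' @return Trial table data frame: subject, age_group, trial, condition,
#'   outcome, theta, alpha (standardized within subject).
#' @export
make_trial_table <- function(events, theta, alpha) {
  stopifnot(nrow(events) == length(theta), length(theta) == length(alpha))
  keep <- events$condition %in% c("match", "mismatch") &
    events$outcome %in% c("miss", "item_only", "pair")
  tab <- data.frame(
    subject = events$subject[keep], age_group = events$age_group[keep],
    trial = events$trial[keep], condition = events$condition[keep],
    outcome = events$outcome[keep],
    theta = theta[keep], alpha = alpha[keep],
    stringsAsFactors = FALSE
  )
  tab$theta <- zscore_within(tab$theta, tab$subject)
  tab$alpha <- zscore_within(tab$alpha, tab$subject)
  tab
}
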