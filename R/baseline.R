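#' Fit the prestimulus baseline model
#'
#' Computes, per channel and frequency, the mean prestimulus power `M` over
#' all trials and all valid baseline time points, and, per channel x
#' frequency x peristimulus time point, the across-trial variance `S2` of
#' activation power.  `M` is computed over all trials regardless of memory
#' condition, which washes out condition differences in the baseline.
#'
#' @param tfr A `"tfr_set"` from [morlet_power()].
#' @param baseline_window Prestimulus window in seconds (default -0.7 to
#'   -0.2).
#' @param activation_window Peristimulus window in seconds (default 0 to 3).
#' @return Object of class `"baseline_model"`: `M` (channels x freqs), `S2`
#'   (channels x freqs x activation times), `n` (trial count), `act_times`,
#'   `mask` (freqs x activation-times validity), `channels`, `freqs`.
#' @export
fit_baseline <- function(tfr, baseline_window = c(-0.7, -0.2),
                         activation_window = c(0, 3)) {
  stopifnot(inherits(tfr, "tfr_set"))
  n <- dim(tfr$power)[1]
  if (n < 2L) stop("baseline variance undefined with fewer than 2 trials")
  bl_idx <- which(tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2])
  if (length(bl_idx) == 0L) stop("baseline window outside the TFR time range")
  act_idx <- which(tfr$times >= activation_window[1] & tfr$times <= activation_window[2])
  if (length(act_idx) == 0L) stop("activation window outside the TFR time range")
  n_ch <- dim(tfr$power)[2]; n_f <- dim(tfr$power)[3]
  M <- matrix(NA_real_, n_ch, n_f, dimnames = list(tfr$channels, NULL))
  for (fi in seq_len(n_f)) {
    ok <- bl_idx[tfr$mask[fi, bl_idx]]
    if (length(ok) == 0L)
      stop("no valid (edge-safe) baseline time point at ", tfr$freqs[fi],
           " Hz; lengthen the epoch or shift the baseline window")
    M[, fi] <- apply(tfr$power[, , fi, ok, drop = FALSE], 2, mean)
  }
  act <- tfr$power[, , , act_idx, drop = FALSE]
  mu <- apply(act, c(2, 3, 4), mean)
  S2 <- apply(act, c(2, 3, 4), stats::var)
  structure(
    list(M = M, S2 = S2, n = n, act_times = tfr$times[act_idx],
         mask = tfr$mask[, act_idx, drop = FALSE], mean_act = mu,
         channels = tfr$channels, freqs = tfr$freqs),
    class = "baseline_model"
  )
}

#' Condition-level baseline-contrast t-map
#'
#' One-sample t of a condition's activation power against the fixed
#' all-trials baseline mean: per channel x frequency x time point,
#' `t = (mean_cond - M) / (sd_cond / sqrt(n_cond))`, where the mean and sd
#' are taken over the condition's trials.  The resulting map is the
#' "baseline-corrected power" entering the group-level analysis.
#'
#' @param tfr A `"tfr_set"`.
#' @param base A `"baseline_model"` fitted on the same trials.
#' @param condition Outcome label selecting trials via `tfr$events$outcome`,
#'   or a logical/integer trial index vector.
#' @return Object of class `"tmap"`: `t` (channels x freqs x times array),
#'   `condition`, `times`, `freqs`, `channels`, `mask`, `n_trials`.
#' @export
condition_tmap <- function(tfr, base, condition) {
  stopifnot(inherits(tfr, "tfr_set"), inherits(base, "baseline_model"))
  if (is.character(condition)) {
    sel <- which(tfr$events$outcome == condition)
    label <- condition
  } else {
    sel <- if (is.logical(condition)) which(condition) else as.integer(condition)
    label <- "custom"
  }
  if (length(sel) < 2L) stop("need at least 2 trials in condition ", label)
  act_idx <- match(base$act_times, tfr$times)
  act <- tfr$power[sel, , , act_idx, drop = FALSE]
  mu <- apply(act, c(2, 3, 4), mean)
  sdv <- sqrt(apply(act, c(2, 3, 4), stats::var))
  nc <- length(sel)
  tval <- sweep(mu, c(1, 2), base$M, "-") / (sdv / sqrt(nc))
  degen <- sdv == 0
  if (any(degen)) {
    warning(sum(degen), " points with zero within-condition variance; t set to 0")
    tval[degen] <- 0
  }
  structure(
    list(t = tval, condition = label, times = base$act_times,
         freqs = base$freqs, channels = base$channels, mask = base$mask,
         n_trials = nc),
    class = "tmap"
  )
}

#' Single-trial baseline-contrast t-values
#'
#' The modified one-sample t statistic in which the sample mean is replaced
#' by single-trial power: elementwise `t = (pow - M) / sqrt(S2 / n)`, with
#' `M` the all-trials baseline mean (per channel x frequency), `S2` the
#' across-all-trials peristimulus variance (per channel x frequency x time)
#' and `n` the trial count.  Places each trial's power relative to the
#' subject's baseline distribution; monotone increasing in `pow` and
#' invariant to a common rescaling of all trials.
#'
#' @param tfr A `"tfr_set"`.
#' @param base A `"baseline_model"` fitted on the same subject's trials.
#' @return Object of class `"single_trial_t"`: `t` (trials x channels x
#'   freqs x times), `times`, `freqs`, `channels`, `mask`, `events`.
#' @export
single_trial_t <- function(tfr, base) {
  stopifnot(inherits(tfr, "tfr_set"), inherits(base, "baseline_model"))
  if (dim(tfr$power)[1] != base$n)
    stop("baseline model was fitted on a different number of trials")
  valid_pts <- aperm(array(base$mask, dim = c(dim(base$mask), dim(tfr$power)[2])),
                     c(3, 1, 2))
  if (any(base$S2[valid_pts] == 0))
    stop("zero across-trial variance at ", sum(base$S2[valid_pts] == 0),
         " valid points; the single-trial statistic is undefined there")
  act_idx <- match(base$act_times, tfr$times)
  act <- tfr$power[, , , act_idx, drop = FALSE]
  denom <- sqrt(base$S2 / base$n)
  tval <- array(NA_real_, dim = dim(act), dimnames = dimnames(act))
  for (tr in seq_len(dim(act)[1])) {
    a <- array(act[tr, , , ], dim = dim(act)[-1])
    tval[tr, , , ] <- (a - as.vector(base$M)) / denom
  }
  structure(
    list(t = tval, times = base$act_times, freqs = base$freqs,
         channels = base$channels, mask = base$mask, events = tfr$events),
    class = "single_trial_t"
  )
}
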