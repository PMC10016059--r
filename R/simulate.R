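#' Simulation parameters for the synthetic study
#'
#' Collects every knob of the synthetic-data generator: design size, EEG
#' sampling, the 1/f background, the two oscillatory components and their
#' scalp weighting, the latent-strength model that couples oscillatory
#' amplitude to memory outcome, and the age moderation.
#'
#' The generative model is a single latent Gaussian encoding strength `m ~
#' N(0,1)` per encoding trial.  Memory outcome follows hard ordered
#' thresholds: miss below `threshold_lower`, pair above the age-group
#' `threshold_upper`, item-only in between; both thresholds are shifted per
#' subject by `N(0, subject_sd)` (between-person memory ability, the source
#' of the GLMM's random-intercept variance).  Oscillatory coupling:
#' \itemize{
#'   \item theta: a peristimulus burst whose amplitude is `theta_base +
#'     theta_gain * b`, where `b = 1(m > upper)` is an all-or-none
#'     associative-binding success signal (smoothed to
#'     `pnorm((m - upper)/binding_scale)` when `binding_scale > 0`) — theta
#'     therefore carries information about the pair/item-only contrast only;
#'   \item alpha: ongoing oscillation whose peristimulus amplitude drops by a
#'     fraction `desync_depth + alpha_gain * attenuation * m'`, where
#'     `m' = m + N(0, coupling_noise)` is the latent seen through trial-level
#'     neural variability (so measured alpha power is a graded correlate, not
#'     a determinant, of the outcome), clipped to `[0, 0.95]`, with
#'     `attenuation = age_attenuation` for older adults and 1 for younger —
#'     the depth-of-processing signal, age-attenuated.
#' }
#' Default thresholds reproduce the observed mean response rates (miss 0.21;
#' pair 0.49 younger, 0.41 older).
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `"sim_params"`.
#' @export
#' @examples
#' p <- sim_params(n_scenes = 10)
#' p$threshold_lower
sim_params <- function(...) {
  montage <- default_montage()
  theta_w <- ifelse(montage$region == "frontocentral", 1,
                    ifelse(montage$region == "central", 0.5, 0.15))
  alpha_w <- ifelse(montage$region == "posterior", 1,
                    ifelse(montage$region == "central", 0.4, 0.15))
  p <- list(
    n_subjects = c(younger = 20L, older = 20L),
    n_scenes = 24L,                    # 120 encoding trials / subject
    sfreq = 100,                       # Hz
    epoch_window = c(-2, 5),           # s, stimulus onset at 0
    # background
    noise_exponent = 1,                # 1/f^exponent power spectrum
    noise_sd = 10,                     # microvolt
    # theta burst (fronto-central)
    theta_freq = 4,                    # Hz
    theta_base = 4,                    # microvolt
    theta_gain = 1,                    # microvolt per unit binding signal
    theta_center = 0.75,               # s, burst envelope center
    theta_width = 0.35,                # s, burst envelope sd
    binding_scale = 0,                 # 0 = all-or-none binding; > 0 smooths
    coupling_noise = 1,                # sd of trial-level neural variability
                                       # between latent strength and alpha power
    # alpha oscillation (posterior)
    alpha_freq = 10,                   # Hz
    alpha_amp = 10,                    # microvolt, prestimulus amplitude
    desync_depth = 0.3,                # mean fractional peristimulus drop
    alpha_gain = 0.15,                 # extra fractional drop per latent SD
    desync_window = c(0.3, 3.0),       # s, full-depth desynchronization
    desync_ramp = 0.25,                # s, on/off ramp
    # latent-strength -> outcome
    threshold_lower = stats::qnorm(0.21),
    threshold_upper = c(younger = stats::qnorm(1 - 0.49),
                        older = stats::qnorm(1 - 0.41)),
    subject_sd = 0.3,
    age_attenuation = 0.2,
    # single-trial FROI measurement noise (t-value scale)
    froi_noise_theta = 2,
    froi_noise_alpha = 3,
    # new-object responding
    false_alarm_rate = 0.15,
    montage = montage,
    theta_weights = stats::setNames(theta_w, montage$channel),
    alpha_weights = stats::setNames(alpha_w, montage$channel),
    seed = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown simulation parameters: ", paste(bad, collapse = ", "))
    p <- utils::modifyList(p, over)
  }
  validate_sim_params(structure(p, class = "sim_params"))
}

#' @noRd
validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (!all(is.finite(c(p$theta_gain, p$alpha_gain, p$theta_base))))
    stop("oscillatory gains must be finite")
  if (p$age_attenuation < 0 || p$age_attenuation > 1)
    stop("age_attenuation must lie in [0, 1]")
  up <- upper_thresholds(p)
  if (any(p$threshold_lower > up))
    stop("threshold_lower must not exceed threshold_upper")
  if (p$sfreq < 2 * max(p$theta_freq, p$alpha_freq))
    stop("sampling rate violates the Nyquist limit for the simulated bands")
  p
}

#' @noRd
upper_thresholds <- function(p) {
  up <- p$threshold_upper
  if (length(up) == 1L && is.null(names(up)))
    up <- c(younger = unname(up), older = unname(up))
  up[c("younger", "older")]
}

#' Simulate behavioral outcomes for one subject
#'
#' Draws the latent encoding strength of every encoding trial and derives the
#' memory outcome from the ordered-threshold model of [sim_params()],
#' together with the injected oscillatory modulations (`theta_amp`,
#' `alpha_desync`) consumed by [simulate_epochs()].
#'
#' Outcomes are defined for old-object test conditions: match/mismatch trials
#' can be `miss`, `item_only` or `pair`; old-new trials (no pair judgment)
#' only `miss` or `item_only`.
#'
#' @param design A [generate_design()] object.
#' @param params A [sim_params()] list.
#' @param subject Subject identifier.
#' @param age_group `"younger"` or `"older"`.
#' @param subject_shift Optional fixed subject-level threshold shift;
#'   defaults to a `N(0, subject_sd)` draw.
#' @param seed Optional integer seed (global RNG state is restored).
#' @return Data frame of class `"trial_meta"`, one row per encoding trial:
#'   subject, age_group, trial, object, scene, condition (the object's test
#'   condition), position, latent, binding, theta_amp, alpha_desync, outcome.
#' @export
simulate_behavior <- function(design, params = sim_params(), subject = "sub01",
                              age_group = c("younger", "older"),
                              subject_shift = NULL, seed = NULL) {
  age_group <- match.arg(age_group)
  stopifnot(inherits(design, "study_design"))
  with_seed(seed, {
    enc <- design$encoding
    n <- nrow(enc)
    tst <- design$test
    cond <- tst$condition[match(enc$object, tst$object)]
    if (is.null(subject_shift)) subject_shift <- stats::rnorm(1, 0, params$subject_sd)
    lo <- params$threshold_lower + subject_shift
    up <- upper_thresholds(params)[[age_group]] + subject_shift
    m <- stats::rnorm(n)
    # alpha sees the latent through trial-level neural noise, so measured
    # alpha power is a graded correlate, not a determinant, of the outcome
    m_eeg <- m + stats::rnorm(n, 0, params$coupling_noise)
    # theta reflects all-or-none associative binding success (optionally
    # smoothed); it carries no information below the pair threshold
    b <- if (params$binding_scale > 0) {
      stats::pnorm((m - up) / params$binding_scale)
    } else {
      as.numeric(m > up)
    }
    att <- if (age_group == "older") params$age_attenuation else 1
    desync <- pmin(pmax(params$desync_depth + params$alpha_gain * att * m_eeg, 0), 0.95)
    outcome <- ifelse(m < lo, "miss", ifelse(m > up, "pair", "item_only"))
    outcome[cond == "old_new" & outcome == "pair"] <- "item_only"
    structure(
      data.frame(
        subject = subject, age_group = age_group, trial = enc$trial,
        object = enc$object, scene = enc$scene, condition = cond,
        position = enc$position, latent = m, binding = b,
        theta_amp = params$theta_base + params$theta_gain * b,
        alpha_desync = desync, outcome = outcome,
        stringsAsFactors = FALSE
      ),
      class = c("trial_meta", "data.frame"),
      subject_shift = subject_shift
    )
  })
}

# 1/f^a background noise, one column per channel, standardized to sd `scale`
#' @noRd
one_over_f_noise <- function(n, n_ch, exponent = 1, scale = 1) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  # hermitian spectrum -> real signal
  re <- matrix(stats::rnorm(nf * n_ch), nf, n_ch) * amp
  im <- matrix(stats::rnorm(nf * n_ch), nf, n_ch) * amp
  spec <- matrix(0 + 0i, n, n_ch)
  spec[1L + f, ] <- complex(real = re, imaginary = im)
  spec[n + 1L - f, ] <- Conj(spec[1L + f, ])
  if (n %% 2L == 0L) spec[nf + 1L, ] <- complex(real = re[nf, ], imaginary = 0)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/") * scale
}

# piecewise-linear 0->1->0 envelope for the desynchronization window
#' @noRd
desync_envelope <- function(times, window, ramp) {
  up <- pmin(pmax((times - (window[1] - ramp)) / ramp, 0), 1)
  down <- pmin(pmax(((window[2] + ramp) - times) / ramp, 0), 1)
  up * down
}

#' Simulate EEG epochs for a set of encoding trials
#'
#' Each 7-s epoch is the sum of independent 1/f background noise per channel,
#' an ongoing alpha oscillation whose peristimulus amplitude is reduced by
#' the trial's injected desynchronization fraction, and a peristimulus theta
#' burst with the trial's injected amplitude.  Both oscillations have a
#' random phase per trial (shared across channels) and fixed per-channel
#' topographic weights; no evoked (phase-locked) component is simulated.
#'
#' @param meta A `"trial_meta"` data frame from [simulate_behavior()].
#' @param params A [sim_params()] list.
#' @param seed Optional integer seed.
#' @return An object of class `"epoch_set"`: list with `data` (trials x
#'   channels x samples array, microvolt), `times` (s), `sfreq`, `channels`
#'   and `events` (= `meta`).
#' @export
simulate_epochs <- function(meta, params = sim_params(), seed = NULL) {
  stopifnot(is.data.frame(meta), all(c("theta_amp", "alpha_desync") %in% names(meta)))
  validate_sim_params(params)
  with_seed(seed, {
    sf <- params$sfreq
    times <- seq(params$epoch_window[1], params$epoch_window[2] - 1 / sf, by = 1 / sf)
    ns <- length(times)
    channels <- params$montage$channel
    n_ch <- length(channels)
    n_tr <- nrow(meta)
    tw <- params$theta_weights[channels]
    aw <- params$alpha_weights[channels]
    denv <- desync_envelope(times, params$desync_window, params$desync_ramp)
    tenv <- exp(-(times - params$theta_center)^2 / (2 * params$theta_width^2)) *
      (times > -3 * params$theta_width + params$theta_center)
    dat <- array(0, dim = c(n_tr, n_ch, ns),
                 dimnames = list(NULL, channels, NULL))
    for (i in seq_len(n_tr)) {
      noise <- t(one_over_f_noise(ns, n_ch, params$noise_exponent, params$noise_sd))
      ph_a <- stats::runif(1, 0, 2 * pi)
      ph_t <- stats::runif(1, 0, 2 * pi)
      alpha_env <- params$alpha_amp * (1 - meta$alpha_desync[i] * denv)
      alpha_sig <- alpha_env * sin(2 * pi * params$alpha_freq * times + ph_a)
      theta_sig <- meta$theta_amp[i] * tenv *
        sin(2 * pi * params$theta_freq * times + ph_t)
      dat[i, , ] <- noise +
        outer(aw, alpha_sig) +
        outer(tw, theta_sig)
    }
    structure(
      list(data = dat, times = times, sfreq = sf, channels = channels,
           events = meta),
      class = "epoch_set"
    )
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("EEG epochs:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat(sprintf("  %.0f Hz, %.1f to %.1f s\n", x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: fresh design, behavioral outcomes and EEG epochs for
#' a single subject.
#'
#' @inheritParams simulate_behavior
#' @param seed Integer seed controlling design, behavior and EEG jointly.
#' @return List with `design`, `meta` and `epochs`.
#' @export
simulate_subject <- function(params = sim_params(), subject = "sub01",
                             age_group = "younger", seed = NULL) {
  with_seed(seed, {
    design <- generate_design(params$n_scenes)
    meta <- simulate_behavior(design, params, subject = subject,
                              age_group = age_group)
    epochs <- simulate_epochs(meta, params)
    list(design = design, meta = meta, epochs = epochs)
  })
}

#' Simulate behavioral events for a whole sample
#'
#' Runs [generate_design()] and [simulate_behavior()] for every subject in
#' both age groups (no EEG), returning the stacked events table used by the
#' behavioral analyses.
#'
#' @param params A [sim_params()] list.
#' @param seed Optional integer seed.
#' @return Data frame with one row per encoding trial and subject.
#' @export
simulate_events <- function(params = sim_params(), seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (grp in c("younger", "older")) {
      for (i in seq_len(params$n_subjects[[grp]])) {
        id <- sprintf("%s_%02d", substr(grp, 1, 1), i)
        design <- generate_design(params$n_scenes)
        out[[id]] <- simulate_behavior(design, params, subject = id,
                                       age_group = grp)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a single-trial predictor table directly from the latent model
#'
#' Generates the model frame of the single-trial analysis without going
#' through EEG synthesis: the injected theta and alpha modulations of each
#' trial (identical maths to [simulate_epochs()]) plus Gaussian measurement
#' noise on the t-value scale (`froi_noise_*`), z-scored within subject.
#' This is the generator's fast path for studying the mixed-model stage at
#' many replicates; the full EEG path must agree with it in sign structure.
#'
#' @param params A [sim_params()] list.
#' @param seed Optional integer seed.
#' @return A trial table (data frame): subject, age_group, trial, condition,
#'   outcome, latent, theta, alpha — `theta`/`alpha` standardized within
#'   subject.
#' @export
simulate_trial_table <- function(params = sim_params(), seed = NULL) {
  with_seed(seed, {
    out <- list()
    for (grp in c("younger", "older")) {
      for (i in seq_len(params$n_subjects[[grp]])) {
        id <- sprintf("%s_%02d", substr(grp, 1, 1), i)
        design <- generate_design(params$n_scenes)
        meta <- simulate_behavior(design, params, subject = id, age_group = grp)
        keep <- meta$condition %in% c("match", "mismatch")
        meta <- meta[keep, ]
        n <- nrow(meta)
        theta_raw <- meta$theta_amp + stats::rnorm(n, 0, params$froi_noise_theta)
        alpha_raw <- -params$alpha_amp * meta$alpha_desync +
          stats::rnorm(n, 0, params$froi_noise_alpha)
        out[[id]] <- data.frame(
          subject = id, age_group = grp, trial = meta$trial,
          condition = meta$condition, outcome = meta$outcome,
          latent = meta$latent,
          theta = as.numeric(scale(theta_raw)),
          alpha = as.numeric(scale(alpha_raw)),
          stringsAsFactors = FALSE
        )
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
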