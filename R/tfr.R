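#' Time-frequency decomposition settings
#'
#' @param freqs Analysis frequencies in Hz (default 2-30 Hz in steps of 2).
#' @param width Wavelet width in cycles (default 7).
#' @param step Output time step in seconds (default 0.050, the sliding
#'   window of the decomposition).
#' @param out_range Output time range in seconds relative to stimulus onset;
#'   the default covers the baseline window through the activation window.
#' @param support Wavelet truncation in units of the temporal standard
#'   deviation `sigma_t = width / (2 pi f)`; points closer than
#'   `support * sigma_t` to an epoch edge are flagged in the validity mask.
#' @return List of class `"tfr_config"`.
#' @export
tfr_config <- function(freqs = seq(2, 30, by = 2), width = 7, step = 0.05,
                       out_range = c(-0.7, 3), support = 3) {
  stopifnot(width >= 3, all(freqs > 0), step > 0, length(out_range) == 2,
            out_range[1] < out_range[2])
  structure(list(freqs = freqs, width = width, step = step,
                 out_range = out_range, support = support),
            class = "tfr_config")
}

# complex Morlet kernel with unit continuous-time energy, truncated at
# +/- support * sigma_t
#' @noRd
morlet_kernel <- function(freq, width, sfreq, support = 3) {
  sigma_t <- width / (2 * pi * freq)
  half <- ceiling(support * sigma_t * sfreq)
  tau <- (-half:half) / sfreq
  w <- exp(-tau^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * tau)
  w / sqrt(sum(Mod(w)^2) / sfreq)
}

#' Morlet wavelet single-trial spectral power
#'
#' Convolves every channel of every epoch with L2-normalized complex Morlet
#' wavelets and returns squared magnitudes sampled on a regular output grid.
#' Power is on a (two-sided) spectral-density-like scale so that broadband
#' input of variance `v` yields band power `v / sfreq`; scaling the signal
#' by `a` scales power by `a^2`.
#'
#' Output points lying within `support * sigma_t` of an epoch edge at a
#' given frequency are marked invalid in the `mask` (they are computed from
#' zero-padded data, never silently dropped).  Requesting output times
#' outside the epoch is an error.
#'
#' @param epochs An `"epoch_set"` (see [simulate_epochs()] / [read_epochs()]).
#' @param cfg A [tfr_config()].
#' @return Object of class `"tfr_set"`: `power` (trials x channels x
#'   frequencies x times array), `times`, `freqs`, `channels`, `mask`
#'   (frequencies x times logical matrix, `TRUE` = valid) and `events`
#'   carried over from the epochs.
#' @export
morlet_power <- function(epochs, cfg = tfr_config()) {
  stopifnot(inherits(epochs, "epoch_set") || is.list(epochs))
  sf <- epochs$sfreq
  et <- epochs$times
  dt <- 1 / sf
  out_times <- seq(cfg$out_range[1], cfg$out_range[2], by = cfg$step)
  idx <- round((out_times - et[1]) * sf) + 1L
  if (any(idx < 1L | idx > length(et)))
    stop("requested output window [", cfg$out_range[1], ", ", cfg$out_range[2],
         "] s is not covered by the epoch [", et[1], ", ", et[length(et)], "] s")
  d <- dim(epochs$data)
  n_tr <- d[1]; n_ch <- d[2]; ns <- d[3]
  n_f <- length(cfg$freqs)
  kernels <- lapply(cfg$freqs, morlet_kernel, width = cfg$width, sfreq = sf,
                    support = cfg$support)
  half <- vapply(kernels, function(k) (length(k) - 1L) / 2L, numeric(1))
  nfft <- stats::nextn(ns + max(lengths(kernels)), 2)
  kern_f <- lapply(kernels, function(k) {
    stats::fft(c(Conj(rev(k)), rep(0, nfft - length(k))))
  })
  pow <- array(NA_real_, dim = c(n_tr, n_ch, n_f, length(out_times)),
               dimnames = list(NULL, epochs$channels, NULL, NULL))
  for (tr in seq_len(n_tr)) {
    x <- matrix(0, nfft, n_ch)
    x[seq_len(ns), ] <- t(epochs$data[tr, , , drop = TRUE])
    xf <- stats::mvfft(x)
    for (fi in seq_len(n_f)) {
      conv <- stats::mvfft(xf * kern_f[[fi]], inverse = TRUE) / nfft
      # y_t (kernel centered on sample t) sits at full-convolution row t + half
      y <- conv[idx + half[fi], , drop = FALSE] * dt
      pow[tr, , fi, ] <- t(Mod(y)^2)
    }
  }
  mask <- matrix(TRUE, n_f, length(out_times))
  for (fi in seq_len(n_f)) {
    marg <- half[fi] * dt
    mask[fi, ] <- (out_times - marg >= et[1]) & (out_times + marg <= et[length(et)])
  }
  structure(
    list(power = pow, times = out_times, freqs = cfg$freqs,
         channels = epochs$channels, mask = mask, events = epochs$events),
    class = "tfr_set"
  )
}

#' @export
print.tfr_set <- function(x, ...) {
  d <- dim(x$power)
  cat("Time-frequency power:", d[1], "trials x", d[2], "channels x",
      d[3], "freqs x", d[4], "times\n")
  cat(sprintf("  %g-%g Hz, %.2f to %.2f s (%d edge-masked points)\n",
              min(x$freqs), max(x$freqs), min(x$times), max(x$times),
              sum(!x$mask)))
  invisible(x)
}

#' Average time-frequency image across trials and channels
#'
#' Diagnostic plot of grand-average power (optionally baseline-ratioed).
#'
#' @param x A `"tfr_set"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tfr_set <- function(x, ...) {
  avg <- apply(x$power, c(3, 4), mean)
  graphics::image(x$times, x$freqs, t(avg), xlab = "time (s)",
                  ylab = "frequency (Hz)", col = grDevices::hcl.colors(64, "viridis"),
                  main = "mean spectral power", ...)
  invisible(x)
}
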