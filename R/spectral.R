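# spectral: Morlet wavelet time-frequency decomposition with an adaptive
# per-frequency cycle count, plus baseline normalization.
#
# Wavelets are L2-normalized complex Morlets with Gaussian SD
# sigma_t(f) = n_cycles(f) / (pi * f). The cycle count is adaptive: at least
# 5 cycles and half the frequency (rounded up) for f >= 5 Hz; below 5 Hz the
# counts shrink to 2-4 cycles so that slow wavelets keep usable support.
# Cells whose wavelet support (3 sigma_t each side) is not fully covered by
# the epoch are marked invalid (NA), never zero-padded.

#' Build a wavelet specification
#'
#' @param freq_range frequency range in Hz (inclusive).
#' @param step frequency step in Hz.
#' @param min_cycles minimum cycle count for f >= 5 Hz.
#' @param low_breaks,low_cycles piecewise cycle map for f < 5 Hz: frequency
#'   break points and the cycle count used up to each break.
#' @param time_step_s time resolution of the output grid in seconds.
#' @return object of class `wavelet_spec` with `freqs_hz`, `n_cycles`,
#'   `sigma_t`, `time_step_s`.
#' @export
build_wavelet_spec <- function(freq_range = c(1, 20), step = 0.5,
                               min_cycles = 5,
                               low_breaks = c(2, 3.5, 4.99),
                               low_cycles = c(2, 3, 4),
                               time_step_s = 0.02) {
  if (step <= 0) stop("frequency step must be positive")
  freqs <- seq(freq_range[1], freq_range[2], by = step)
  n_cycles <- vapply(freqs, function(f) {
    if (f >= 5) return(max(min_cycles, ceiling(f / 2)))
    low_cycles[findInterval(f, c(-Inf, low_breaks), left.open = TRUE)]
  }, numeric(1))
  structure(list(freqs_hz = freqs, n_cycles = n_cycles,
                 sigma_t = n_cycles / (pi * freqs),
                 time_step_s = time_step_s),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %d frequencies %g-%g Hz, cycles %g-%g, step %g ms\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              min(x$n_cycles), max(x$n_cycles), 1000 * x$time_step_s))
  invisible(x)
}

# L2-normalized complex Morlet kernel, truncated at +/- 3 sigma_t.
morlet_kernel <- function(f, sigma_t, fs) {
  h <- ceiling(3 * sigma_t * fs)
  t <- (-h:h) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Extract event-locked epochs from a continuous signal
#'
#' @param signal numeric signal.
#' @param fs sampling rate in Hz.
#' @param centers_s lock points in seconds (0-based time).
#' @param half_s epoch half-width in seconds.
#' @return list: `epochs` (matrix time x events), `time_s` (epoch time axis
#'   relative to the lock point), `kept` (logical; events too close to the
#'   recording edge are dropped).
#' @export
extract_epochs <- function(signal, fs, centers_s, half_s = 3) {
  h <- round(half_s * fs)
  cs <- round(centers_s * fs) + 1L
  kept <- cs - h >= 1L & cs + h <= length(signal)
  ep <- vapply(cs[kept], function(c0) signal[(c0 - h):(c0 + h)],
               numeric(2L * h + 1L))
  list(epochs = matrix(ep, nrow = 2L * h + 1L),
       time_s = (-h:h) / fs, kept = kept)
}

#' Morlet time-frequency decomposition of epoched data
#'
#' @param epochs matrix, time x events, all sharing the epoch time axis
#'   `epoch_time_s` relative to the lock point.
#' @param fs sampling rate of the epochs in Hz.
#' @param spec a [build_wavelet_spec()] object.
#' @param epoch_time_s epoch time axis (seconds relative to lock).
#' @param t_range output time range (seconds relative to lock).
#' @param lock label of the lock point (`ripple_peak`, `control_center`,
#'   `spindle_trough`, ...).
#' @return object of class `tfr_stack`: complex `coeffs`
#'   (event x frequency x time), `freq_hz`, `time_s`, `valid`
#'   (frequency x time), `lock`. Cells with incomplete wavelet support are
#'   NA and marked invalid.
#' @export
compute_tfr <- function(epochs, fs, spec, epoch_time_s,
                        t_range = c(-1, 1), lock = "ripple_peak") {
  epochs <- as.matrix(epochs)
  nt <- nrow(epochs); nev <- ncol(epochs)
  if (nt != length(epoch_time_s))
    stop("epoch_time_s must match the epoch length")
  step <- max(1L, round(spec$time_step_s * fs))
  out_idx <- which(epoch_time_s >= t_range[1] - 1e-9 &
                   epoch_time_s <= t_range[2] + 1e-9)
  out_idx <- out_idx[seq(1L, length(out_idx), by = step)]
  time_s <- epoch_time_s[out_idx]
  nf <- length(spec$freqs_hz)
  maxlen <- 2L * ceiling(3 * max(spec$sigma_t) * fs) + 1L
  M <- nextpow2(nt + maxlen)
  X <- stats::mvfft(rbind(epochs, matrix(0, M - nt, nev)))
  coeffs <- array(NA_complex_, c(nev, nf, length(time_s)))
  valid <- matrix(TRUE, nf, length(time_s))
  for (k in seq_len(nf)) {
    ker <- morlet_kernel(spec$freqs_hz[k], spec$sigma_t[k], fs)
    h <- (length(ker) - 1L) / 2L
    kpad <- complex(length.out = M)
    kpad[1:(h + 1L)] <- ker[(h + 1L):(2L * h + 1L)]
    kpad[(M - h + 1L):M] <- ker[1:h]
    K <- stats::fft(kpad)
    conv <- stats::mvfft(X * K, inverse = TRUE) / M
    coeffs[, k, ] <- t(conv[out_idx, , drop = FALSE])
    bad <- time_s - 3 * spec$sigma_t[k] < epoch_time_s[1] - 1e-9 |
           time_s + 3 * spec$sigma_t[k] > epoch_time_s[nt] + 1e-9
    if (any(bad)) {
      valid[k, bad] <- FALSE
      coeffs[, k, bad] <- NA_complex_
    }
  }
  structure(list(coeffs = coeffs, freq_hz = spec$freqs_hz, time_s = time_s,
                 valid = valid, lock = lock),
            class = "tfr_stack")
}

#' @export
print.tfr_stack <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<tfr_stack> %d events x %d freqs (%g-%g Hz) x %d times (%g..%g s), lock=%s\n",
              d[1], d[2], min(x$freq_hz), max(x$freq_hz), d[3],
              min(x$time_s), max(x$time_s), x$lock))
  invisible(x)
}

#' Power of a TFR stack
#' @param tfr a `tfr_stack` (or complex array).
#' @return numeric array event x frequency x time of squared magnitudes.
#' @export
tfr_power <- function(tfr) {
  co <- if (inherits(tfr, "tfr_stack")) tfr$coeffs else tfr
  Mod(co)^2
}

#' Percentage power change relative to a pre-event baseline
#'
#' @param power numeric array event x frequency x time.
#' @param time_s time axis matching the third dimension.
#' @param window_s baseline window (default -2 to -1.5 s).
#' @return array of the same shape: `100 * (P - mean_base) / mean_base`,
#'   the baseline mean taken per event and frequency.
#' @export
baseline_percent_change <- function(power, time_s, window_s = c(-2, -1.5)) {
  sel <- time_s >= window_s[1] & time_s <= window_s[2]
  if (!any(sel)) stop("baseline window outside the time axis")
  base <- apply(power[, , sel, drop = FALSE], c(1, 2), mean)
  if (any(base == 0, na.rm = TRUE)) stop("zero baseline power")
  sweep(sweep(power, c(1, 2), base, `-`), c(1, 2), base, `/`) * 100
}
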