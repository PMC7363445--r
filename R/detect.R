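# event_detection: discrete spindle and sharp-wave-ripple detection by
# band-limited RMS thresholding with duration and cycle constraints, plus
# the frequency-profile false-positive filter.
#
# Thresholds are data-derived: mean + k * SD of the smoothed band RMS over
# all artifact-free NREM samples. Because both thresholds scale with the
# data, the detected event set is invariant to rescaling the signal.

#' Detector parameter sets
#'
#' Returns the canonical parameters for the spindle (12-16 Hz, 200 ms RMS
#' windows, thresholds mean + 1.25 / + 5 SD, durations 0.4-3 s) or ripple
#' detector (80-120 Hz, 20 ms RMS windows, thresholds mean + 2.5 / + 9 SD,
#' durations 38-500 ms, at least 3 raw cycles). Any field can be overridden
#' through `...`.
#'
#' @param kind `"spindle"` or `"ripple"`.
#' @param ... overrides for individual fields.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(kind = c("spindle", "ripple"), ...) {
  kind <- match.arg(kind)
  base <- if (kind == "spindle") list(
    kind = kind, band_hz = c(12, 16),
    rms_window_s = 0.2, smooth_window_s = 0.2,
    thresh_sd = 1.25, upper_sd = 5,
    min_dur_s = 0.4, max_dur_s = 3, min_cycles = NULL,
    cycle_band_hz = c(0.3, 300),
    profile_band_hz = c(12, 16), profile_freqs = c(9, 19, 0.5),
    profile_halfwindow_s = 0.75, profile_avg_halfwindow_s = 0.5,
    prominence_frac = 0.2, peak_sign = "trough")
  else list(
    kind = kind, band_hz = c(80, 120),
    rms_window_s = 0.02, smooth_window_s = 0.02,
    thresh_sd = 2.5, upper_sd = 9,
    min_dur_s = 0.038, max_dur_s = 0.5, min_cycles = 3,
    cycle_band_hz = c(30, 300),
    profile_band_hz = c(80, 120), profile_freqs = c(65, 135, 2),
    profile_halfwindow_s = 0.1, profile_avg_halfwindow_s = 0.05,
    prominence_frac = 0.2, peak_sign = "peak")
  p <- utils::modifyList(base, list(...))
  stopifnot(p$band_hz[1] < p$band_hz[2], p$thresh_sd < p$upper_sd,
            p$min_dur_s <= p$max_dur_s)
  structure(p, class = "detector_params")
}

#' Smoothed moving-RMS envelope
#'
#' Centered moving RMS over `window_s` followed by a centered moving average
#' of the same default length; windows shrink at the edges.
#'
#' @param x numeric signal (typically band-pass filtered).
#' @param fs sampling rate in Hz.
#' @param window_s RMS window length in seconds.
#' @param smooth_s smoothing window length in seconds.
#' @return envelope, same length as `x`.
#' @export
rms_envelope <- function(x, fs, window_s = 0.2, smooth_s = window_s) {
  if (length(x) == 0) stop("empty signal")
  w <- round(window_s * fs)
  if (w < 2) stop("RMS window must span at least 2 samples")
  env <- sqrt(moving_mean(x^2, w))
  moving_mean(env, max(1, round(smooth_s * fs)))
}

#' Count raw-signal cycles inside an event
#'
#' Operationalizes a "minimum of three cycles in the raw EEG" criterion on a
#' broadly filtered trace: half-waves are delimited by zero crossings and a
#' half-wave counts only if its extremum reaches `min_amp_frac` of the
#' event's maximum absolute amplitude; a cycle is two qualifying half-waves.
#'
#' @param signal raw signal.
#' @param fs sampling rate in Hz.
#' @param onset_s,offset_s event boundaries in seconds.
#' @param band_hz broad filter band (0.3-300 Hz, capped below Nyquist).
#' @param min_amp_frac amplitude fraction for a qualifying half-wave.
#' @param prefiltered optional precomputed broad-band trace (to avoid
#'   re-filtering per event).
#' @return integer cycle count.
#' @export
count_raw_cycles <- function(signal, fs, onset_s, offset_s,
                             band_hz = c(0.3, 300), min_amp_frac = 0.25,
                             prefiltered = NULL) {
  xf <- if (!is.null(prefiltered)) prefiltered
        else bandpass_filter(signal, fs, band_hz[1], min(band_hz[2], 0.45 * fs))
  a <- max(1L, round(onset_s * fs) + 1L)
  b <- min(length(xf), round(offset_s * fs))
  seg <- xf[a:b]
  if (length(seg) < 3 || all(seg == 0)) return(0L)
  amp_min <- min_amp_frac * max(abs(seg))
  s <- sign(seg)
  s[s == 0] <- 1
  cross <- which(diff(s) != 0)
  bounds <- c(0L, cross, length(seg))
  n_half <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    hw <- seg[(bounds[i] + 1L):bounds[i + 1L]]
    if (max(abs(hw)) >= amp_min) n_half <- n_half + 1L
  }
  as.integer(floor(n_half / 2))
}

# Local maxima and their prominences (classic definition: height above the
# higher of the two lowest valleys separating the peak from higher ground).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), prominence = numeric()))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx)) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(idx, function(p) {
    left <- y[seq_len(p - 1L)]
    higher_l <- which(left > y[p])
    lo_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(p - 1L)]) else min(left)
    right <- y[(p + 1L):n]
    higher_r <- which(right > y[p])
    lo_r <- if (length(higher_r)) min(y[(p + 1L):(p + min(higher_r) - 1L)]) else min(right)
    y[p] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Frequency-profile validation of a candidate event
#'
#' Computes a wavelet TFR locked to the event peak (spindles: 9-19 Hz in
#' 0.5 Hz steps over +/- 750 ms; ripples: 65-135 Hz in 2 Hz steps over
#' +/- 100 ms; 2 ms time steps), averages magnitude over the central span,
#' and accepts the event only if the resulting frequency profile has a peak
#' inside the band of interest whose prominence reaches `prominence_frac`
#' of the profile maximum. Broadband transients fail this check.
#'
#' @param signal raw signal.
#' @param fs sampling rate in Hz.
#' @param peak_s event peak time in seconds.
#' @param params a [detector_params()] list.
#' @return logical; `FALSE` with attribute `reason` when rejected (including
#'   events too close to the recording edge for the profile window).
#' @export
frequency_profile_ok <- function(signal, fs, peak_s, params) {
  pf <- params$profile_freqs
  spec <- build_wavelet_spec(c(pf[1], pf[2]), pf[3], time_step_s = 0.002)
  half <- params$profile_halfwindow_s + 3 * max(spec$sigma_t) + 0.05
  c0 <- round(peak_s * fs) + 1L
  h <- round(half * fs)
  if (c0 - h < 1L || c0 + h > length(signal))
    return(structure(FALSE, reason = "edge"))
  seg <- signal[(c0 - h):(c0 + h)]
  tfr <- compute_tfr(matrix(seg, ncol = 1), fs, spec, (-h:h) / fs,
                     t_range = c(-params$profile_halfwindow_s,
                                 params$profile_halfwindow_s),
                     lock = "event_peak")
  avg_sel <- abs(tfr$time_s) <= params$profile_avg_halfwindow_s + 1e-9
  profile <- apply(Mod(tfr$coeffs[1, , avg_sel, drop = FALSE]), 2, mean)
  pk <- find_peaks(profile)
  if (!nrow(pk)) return(structure(FALSE, reason = "no_peak"))
  # the profile maximum itself must be an in-band peak that declines by at
  # least prominence_frac of the maximum on both sides
  top <- pk[which.max(profile[pk$index]), ]
  f_top <- tfr$freq_hz[top$index]
  ok <- f_top >= params$profile_band_hz[1] &&
    f_top <= params$profile_band_hz[2] &&
    top$prominence >= params$prominence_frac * max(profile)
  if (!ok) return(structure(FALSE, reason = "profile_flat"))
  TRUE
}

#' Detect discrete events by RMS-envelope thresholding
#'
#' Threshold statistics (mean, SD of the smoothed band RMS) are computed
#' over artifact-free NREM samples only. Candidate events are maximal
#' supra-threshold runs meeting the duration bounds; candidates whose
#' envelope exceeds the upper threshold anywhere are discarded, as are
#' candidates whose padded span (onset - pad to offset + pad, pad = profile
#' half-window) leaves the artifact-free NREM pool, candidates with too few
#' raw cycles, and candidates failing the frequency-profile check. Spindle
#' peaks are placed on the deepest filtered trough, ripple peaks on the
#' maximum positive filtered peak.
#'
#' @param signal numeric signal in uV.
#' @param fs sampling rate in Hz.
#' @param artifact_mask per-sample logical (TRUE = artifact), or an
#'   `artifact_mask` object.
#' @param nrem per-sample logical NREM mask.
#' @param params a [detector_params()] list.
#' @param channel channel label stored in the event table.
#' @return event data.frame (see [empty_events()]); attribute `rejections`
#'   tabulates why candidates were dropped, attribute `threshold` records
#'   the thresholds applied.
#' @export
detect_events <- function(signal, fs, artifact_mask, nrem, params,
                          channel = "NC") {
  if (inherits(artifact_mask, "artifact_mask"))
    artifact_mask <- artifact_mask$mask
  stopifnot(length(artifact_mask) == length(signal),
            length(nrem) == length(signal))
  xf <- bandpass_filter(signal, fs, params$band_hz[1],
                        min(params$band_hz[2], 0.49 * fs))
  env <- rms_envelope(xf, fs, params$rms_window_s, params$smooth_window_s)
  pool <- nrem & !artifact_mask
  if (!any(pool)) stop("no artifact-free NREM samples to derive thresholds")
  mu <- mean(env[pool]); sdv <- stats::sd(env[pool])
  thr <- mu + params$thresh_sd * sdv
  upper <- mu + params$upper_sd * sdv
  if (thr < 1e-6)   # numerically silent band: no physical events
    return(structure(empty_events(),
                     rejections = c(duration = 0L, masked = 0L, upper = 0L,
                                    cycles = 0L, profile = 0L, edge = 0L),
                     threshold = c(lower = thr, upper = upper, mean = mu,
                                   sd = sdv)))
  runs <- runs_true(env > thr)
  rej <- c(duration = 0L, masked = 0L, upper = 0L, cycles = 0L,
           profile = 0L, edge = 0L)
  pad <- round(params$profile_halfwindow_s * fs)
  broad <- if (!is.null(params$min_cycles))
    bandpass_filter(signal, fs, params$cycle_band_hz[1],
                    min(params$cycle_band_hz[2], 0.45 * fs)) else NULL
  out <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    dur <- (b - a + 1) / fs
    if (dur < params$min_dur_s || dur > params$max_dur_s) {
      rej["duration"] <- rej["duration"] + 1L; next
    }
    if (a - pad < 1 || b + pad > length(signal)) {
      rej["edge"] <- rej["edge"] + 1L; next
    }
    if (!all(pool[(a - pad):(b + pad)])) {
      rej["masked"] <- rej["masked"] + 1L; next
    }
    if (any(env[a:b] > upper)) {
      rej["upper"] <- rej["upper"] + 1L; next
    }
    if (!is.null(params$min_cycles) &&
        count_raw_cycles(signal, fs, (a - 1) / fs, b / fs,
                         prefiltered = broad) < params$min_cycles) {
      rej["cycles"] <- rej["cycles"] + 1L; next
    }
    pk_rel <- if (params$peak_sign == "trough") which.min(xf[a:b])
              else which.max(xf[a:b])
    pk <- a + pk_rel - 1L
    ok <- frequency_profile_ok(signal, fs, (pk - 1) / fs, params)
    if (!isTRUE(ok)) {
      key <- if (identical(attr(ok, "reason"), "edge")) "edge" else "profile"
      rej[key] <- rej[key] + 1L; next
    }
    out[[length(out) + 1L]] <- data.frame(
      id = NA_integer_, channel = channel, kind = params$kind,
      onset_s = (a - 1) / fs, offset_s = b / fs, peak_s = (pk - 1) / fs,
      duration_s = dur, peak_amp_uv = xf[pk], stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_events()
  if (nrow(ev)) ev$id <- seq_len(nrow(ev))
  attr(ev, "rejections") <- rej
  attr(ev, "threshold") <- c(lower = thr, upper = upper, mean = mu, sd = sdv)
  validate_events(ev)
}

#' Event density per minute of clean NREM
#'
#' @param events event data.frame.
#' @param clean_nrem_s artifact-free NREM duration in seconds.
#' @return events per minute.
#' @export
event_density <- function(events, clean_nrem_s) {
  if (clean_nrem_s <= 0) stop("clean NREM duration must be positive")
  nrow(events) / (clean_nrem_s / 60)
}

#' Match detected events to ground truth by temporal overlap
#'
#' Any overlap between a detected event and a true event of the same kind
#' counts as a hit; precision, recall and F1 follow.
#'
#' @param detected,truth event data.frames (same channel/kind selection).
#' @return list with `precision`, `recall`, `f1`, `n_detected`, `n_truth`.
#' @export
match_events <- function(detected, truth) {
  overlaps <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(logical(nrow(a)))
    vapply(seq_len(nrow(a)), function(i)
      any(a$onset_s[i] < b$offset_s & a$offset_s[i] > b$onset_s), TRUE)
  }
  tp_det <- overlaps(detected, truth)
  tp_tru <- overlaps(truth, detected)
  precision <- if (nrow(detected)) mean(tp_det) else NA_real_
  recall <- if (nrow(truth)) mean(tp_tru) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_detected = nrow(detected), n_truth = nrow(truth))
}
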