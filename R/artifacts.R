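# artifact_detection: the three automated artifact detectors and the
# padding / short-gap rules producing a per-sample ArtifactMask.
#
# Thresholds for the gradient and high-frequency detectors are data-derived
# (median +/- k * IQR) and computed separately per sleep stage when a stage
# vector is supplied; unscored samples fall back to the global threshold.

# Apply a per-stage statistic -> logical exceedance vector.
stagewise_flags <- function(x, stages, flag_fun) {
  if (is.null(stages)) return(flag_fun(x, rep(TRUE, length(x))))
  out <- logical(length(x))
  labs <- unique(stages)
  labs <- labs[labs != "unscored"]
  for (s in labs) {
    idx <- stages == s
    out[idx] <- flag_fun(x, idx)[idx]
  }
  if (any(stages == "unscored")) {
    idx <- stages == "unscored"
    out[idx] <- flag_fun(x, rep(TRUE, length(x)))[idx]
  }
  out
}

#' Amplitude artifact detection
#'
#' Flags samples whose 0.3-150 Hz filtered value exceeds
#' +/- `threshold_uv`. The 0.3 Hz edge is a causal first-order high-pass
#' (6 dB/octave, as in clinical acquisition chains), so step-like
#' excursions keep their onset amplitude; the 150 Hz edge is zero-phase.
#'
#' @param signal numeric signal in uV.
#' @param fs sampling rate in Hz; must exceed 300 Hz so the 0.3-150 Hz
#'   analysis band is realizable.
#' @param threshold_uv absolute amplitude threshold (750 uV).
#' @return integer matrix of flagged sample intervals (`start`, `end`).
#' @export
detect_amplitude_artifacts <- function(signal, fs, threshold_uv = 750) {
  if (fs < 300) stop("amplitude artifact detection requires fs >= 300 Hz")
  xf <- acquisition_filter(signal, fs, 0.3, 150)
  runs_true(abs(xf) > threshold_uv)
}

#' Gradient artifact detection
#'
#' Computes the first difference of the 0.3-150 Hz filtered signal and flags
#' samples where it leaves `median +/- k * IQR` (two-sided). A degenerate
#' IQR of zero (constant-derivative signal) yields no flags: a signal with
#' constant slope has no transient.
#'
#' @inheritParams detect_amplitude_artifacts
#' @param k_iqr IQR multiplier (6).
#' @param stages optional per-sample stage labels; thresholds are computed
#'   per stage.
#' @export
detect_gradient_artifacts <- function(signal, fs, k_iqr = 6, stages = NULL) {
  if (length(signal) < 2) stop("signal must have at least 2 samples")
  if (fs < 300) stop("gradient artifact detection requires fs >= 300 Hz")
  xf <- acquisition_filter(signal, fs, 0.3, 150)
  d <- c(diff(xf), 0)
  flag_fun <- function(x, idx) {
    med <- stats::median(x[idx])
    iqr <- stats::IQR(x[idx])
    # degenerate spread (constant-derivative signal, up to filter start-up
    # transients and numerical noise): no transients to flag; the sub-nV
    # floor guards numerically silent channels
    # (0.01 uV is far below any EEG quantization step)
    if (iqr <= 1e-9 * max(abs(x), 1e-300) || k_iqr * iqr < 0.01)
      return(logical(length(x)))
    x > med + k_iqr * iqr | x < med - k_iqr * iqr
  }
  runs_true(stagewise_flags(d, stages, flag_fun))
}

#' High-frequency burst artifact detection
#'
#' High-passes the signal at 150 Hz, computes a 100 ms moving RMS, and flags
#' contiguous runs above `median + k * IQR` lasting at least `min_dur_s`.
#' Because the centered RMS window smears a burst by up to half a window on
#' each side, the run criterion is applied after correcting for that smear
#' (a physical burst of `min_dur_s` produces a supra-threshold run of about
#' `min_dur_s` plus the window length); a degenerate IQR of zero (no
#' high-frequency content) yields no flags.
#'
#' @inheritParams detect_gradient_artifacts
#' @param k_iqr IQR multiplier (4).
#' @param min_dur_s minimum burst duration in seconds (0.1).
#' @param rms_window_s RMS window length in seconds (0.1).
#' @export
detect_hf_burst_artifacts <- function(signal, fs, k_iqr = 4, min_dur_s = 0.1,
                                      rms_window_s = 0.1, stages = NULL) {
  if (fs <= 300) stop("high-frequency burst detection requires fs > 300 Hz")
  xf <- bandpass_filter(signal, fs, low = 150, high = NULL)
  env <- sqrt(moving_mean(xf^2, round(rms_window_s * fs)))
  flag_fun <- function(x, idx) {
    med <- stats::median(x[idx])
    iqr <- stats::IQR(x[idx])
    # no measurable high-frequency content: nothing to flag; bursts below
    # 0.5 uV RMS are sub-physiological (filter-edge numerics, quantization)
    if (iqr == 0 || med + k_iqr * iqr < 1e-6) return(logical(length(x)))
    x > med + k_iqr * iqr & x > 0.5
  }
  iv <- runs_true(stagewise_flags(env, stages, flag_fun))
  min_run <- round((min_dur_s + 0.75 * rms_window_s) * fs)
  iv[iv[, 2] - iv[, 1] + 1 >= min_run, , drop = FALSE]
}

#' Combine artifact intervals into a final per-sample mask
#'
#' Every detected interval is padded by +/- `pad_s`; artifact-free gaps
#' shorter than `min_clean_s` are then converted to artifacts with
#' provenance `short_gap`.
#'
#' @param intervals named list of interval matrices per artifact class
#'   (as returned by the `detect_*_artifacts` functions).
#' @param fs sampling rate in Hz.
#' @param n_total recording length in samples.
#' @param pad_s padding applied to each detected interval (0.25 s).
#' @param min_clean_s minimum length of a clean gap between artifacts (3 s).
#' @return an object of class `artifact_mask`: `mask` (per-sample logical),
#'   `intervals` (padded, per class including `short_gap`), `params_used`.
#' @export
finalize_mask <- function(intervals, fs, n_total, pad_s = 0.25,
                          min_clean_s = 3) {
  pad <- round(pad_s * fs)
  padded <- lapply(intervals, function(iv) {
    if (is.null(iv) || nrow(iv) == 0)
      return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
    merge_intervals(pad_intervals(iv, pad, n_total))
  })
  mask <- Reduce(`|`, lapply(padded, intervals_to_mask, n = n_total),
                 logical(n_total))
  # close clean gaps shorter than min_clean_s *between* artifacts
  short_gap <- matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end")))
  art_iv <- runs_true(mask)
  if (nrow(art_iv) > 1) {
    gaps_start <- art_iv[-nrow(art_iv), 2] + 1L
    gaps_end <- art_iv[-1, 1] - 1L
    short <- (gaps_end - gaps_start + 1L) < round(min_clean_s * fs)
    if (any(short)) {
      short_gap <- cbind(start = gaps_start[short], end = gaps_end[short])
      mask <- mask | intervals_to_mask(short_gap, n_total)
    }
  }
  padded$short_gap <- short_gap
  structure(list(mask = mask, intervals = padded,
                 params_used = list(pad_s = pad_s, min_clean_s = min_clean_s)),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %.1f%% of %d samples flagged\n",
              100 * mean(x$mask), length(x$mask)))
  for (cls in names(x$intervals))
    cat(sprintf("  %-10s %d intervals\n", cls, nrow(x$intervals[[cls]])))
  invisible(x)
}

#' Run all three artifact detectors on a recording
#'
#' Applies the amplitude, gradient and high-frequency burst detectors to
#' each channel (thresholds per sleep stage when a hypnogram is given),
#' finalizes per-channel masks, and returns their union for pooled
#' analyses.
#'
#' @param recording an `eeg_recording`.
#' @param hypnogram optional `hypnogram` for stage-wise thresholds.
#' @param pad_s,min_clean_s see [finalize_mask()].
#' @return list with `per_channel` (list of `artifact_mask`) and `combined`
#'   (logical union mask).
#' @export
detect_artifacts <- function(recording, hypnogram = NULL, pad_s = 0.25,
                             min_clean_s = 3) {
  n <- n_samples(recording)
  stages <- if (!is.null(hypnogram))
    stage_per_sample(hypnogram, recording$fs, n) else NULL
  per_channel <- lapply(seq_len(ncol(recording$signals)), function(ch) {
    x <- recording$signals[, ch]
    finalize_mask(list(
      amplitude = detect_amplitude_artifacts(x, recording$fs),
      gradient = detect_gradient_artifacts(x, recording$fs, stages = stages),
      hf_burst = detect_hf_burst_artifacts(x, recording$fs, stages = stages)),
      recording$fs, n, pad_s, min_clean_s)
  })
  names(per_channel) <- recording$channel_names
  combined <- Reduce(`|`, lapply(per_channel, `[[`, "mask"), logical(n))
  list(per_channel = per_channel, combined = combined)
}

#' Write a per-sample binary artifact-mask sidecar
#'
#' One byte per sample (0 = clean, 1 = artifact), little-endian, with a
#' JSON header (`<path>.json`) recording the length and sampling rate.
#'
#' @param mask an `artifact_mask`.
#' @param fs sampling rate in Hz.
#' @param path output path for the binary sidecar.
#' @export
write_mask_sidecar <- function(mask, fs, path) {
  jsonlite::write_json(list(n_samples = length(mask$mask), fs = fs,
                            dtype = "uint8"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(mask$mask), con, size = 1L)
  invisible(path)
}

#' Export an artifact mask as an interval table
#'
#' @param mask an `artifact_mask`.
#' @param fs sampling rate in Hz.
#' @param path optional TSV path; when given the table is written there.
#' @return data.frame with `start_s`, `end_s`, `class`.
#' @export
mask_intervals_table <- function(mask, fs, path = NULL) {
  tabs <- lapply(names(mask$intervals), function(cls) {
    iv <- mask$intervals[[cls]]
    if (nrow(iv) == 0) return(NULL)
    data.frame(start_s = (iv[, 1] - 1) / fs, end_s = iv[, 2] / fs,
               class = cls)
  })
  out <- do.call(rbind, tabs)
  if (is.null(out))
    out <- data.frame(start_s = numeric(), end_s = numeric(),
                      class = character())
  out <- out[order(out$start_s), , drop = FALSE]
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
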