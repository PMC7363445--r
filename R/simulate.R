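# synthetic_data: a statistical phantom of a two-channel sleep night
# (neocortical "NC" and hippocampal "HIPP") with ground-truth spindles,
# sharp-wave ripples, cross-regional coupling, artifacts and a hypnogram.
#
# The phantom is not a biophysical model: it is built so that every
# downstream stage (artifact rejection, RMS detection with data-derived
# thresholds, surrogate controls, wavelet connectivity, permutation
# statistics) can be validated against known truth. Because detection
# thresholds are derived from the data (mean + k SD of the band RMS), the
# background must carry realistic in-band variability - slow amplitude
# modulation, a broadband noise floor, and occasional sub-artifact broadband
# transients - otherwise the upper RMS cut-offs would reject every genuine
# event. Amplitudes default to values giving near-ceiling detector recall.

#' Simulation configuration
#'
#' Builds the configuration for [generate_recording()]. All amplitudes are
#' in uV, durations in seconds, rates in events per minute.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param background list: `pink_exponent` (1/f slope), `rms_uv` (pink
#'   component RMS), `white_rms_uv` (broadband floor RMS), `so_freq`,
#'   `so_amp_uv` (slow-oscillation sine, NREM-gated), `mod_depth` and
#'   `mod_freq` (slow gain modulation of the noise background), `transient`
#'   (list: `rate_per_min`, `amp_uv`, `dur_range_s`, `band_hz` - sub-artifact
#'   broadband bursts emulating interictal/muscle activity).
#' @param spindle_model list: `freq_hz`, `dur_range_s`, `amp_uv` (median
#'   envelope peak), `amp_sdlog` (log-normal spread), `rate_per_min`
#'   (uncoupled spindles per channel).
#' @param ripple_model list: `freq_hz`, `dur_range_s`, `amp_uv`, `amp_sdlog`,
#'   `sharpwave_freq_hz`, `sharpwave_amp_uv`, `rate_per_min`, `min_gap_s`.
#' @param coupling list: `p_couple` (probability a ripple is preceded by
#'   spindles in both channels), `lag_nc_s` and `lag_hipp_s` (spindle onset
#'   precedes ripple peak by this much), `jitter_s` (SD of lag jitter,
#'   truncated at 3 SD), `direction_delay_s` (delay of the HIPP spindle
#'   carrier relative to NC), `direction_mix` (fraction of the HIPP carrier
#'   inherited from NC; 1 = pure delayed copy).
#' @param duration_effect slope linking coupled-spindle amplitude to ripple
#'   duration: amplitude scales by `1 + slope * (dur - median)/median`.
#' @param artifact_injection list of counts and amplitudes per artifact
#'   class; see [inject_artifacts()].
#' @param hypnogram optional explicit `hypnogram`; by default a stereotyped
#'   night (wake onset, S2/SWS NREM blocks, one REM block) is generated.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 1800, fs = 1000,
                       background = list(),
                       spindle_model = list(),
                       ripple_model = list(),
                       coupling = list(),
                       duration_effect = 0,
                       artifact_injection = list(),
                       hypnogram = NULL,
                       seed = 1L) {
  bg <- utils::modifyList(list(
    pink_exponent = 1, rms_uv = 15, white_rms_uv = 4,
    so_freq = 0.8, so_amp_uv = 20,
    mod_depth = 0.6, mod_freq = 0.03,
    transient = list(rate_per_min = 6, amp_uv = 7, dur_range_s = c(0.05, 0.2),
                     band_hz = c(25, 70)),
    hf_noise = list(rms_uv = 3, band_hz = c(60, 250)),
    spikes = list(rate_per_min = 60, amp_uv = 18, amp_sdlog = 0.25,
                  width_s = 0.003)), background)
  sp <- utils::modifyList(list(
    freq_hz = 13.5, dur_range_s = c(0.8, 1.8), amp_uv = 27, amp_sdlog = 0.1,
    rate_per_min = 5), spindle_model)
  rp <- utils::modifyList(list(
    freq_hz = 90, dur_range_s = c(0.13, 0.28), amp_uv = 23, amp_sdlog = 0.07,
    sharpwave_freq_hz = 3, sharpwave_amp_uv = 40,
    rate_per_min = 8, min_gap_s = 2.5), ripple_model)
  cp <- utils::modifyList(list(
    p_couple = 0.8, lag_nc_s = 0.225, lag_hipp_s = 0.075, jitter_s = 0.015,
    direction_delay_s = 0.02, direction_mix = 0.8), coupling)
  ai <- utils::modifyList(list(
    n_amplitude = 0, n_gradient = 0, n_hf = 0,
    amplitude_uv = 900, amp_dur_s = 0.3,
    step_uv = 400, hf_amp_uv = 120, hf_freq_hz = 200, hf_dur_s = 0.15),
    artifact_injection)
  cfg <- list(duration_s = duration_s, fs = fs, background = bg,
              spindle_model = sp, ripple_model = rp, coupling = cp,
              duration_effect = duration_effect, artifact_injection = ai,
              hypnogram = hypnogram, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$fs > 0)
  sp <- cfg$spindle_model; rp <- cfg$ripple_model; cp <- cfg$coupling
  if (sp$dur_range_s[1] < 0.4 || sp$dur_range_s[2] > 3)
    stop("spindle durations must lie within [0.4, 3] s")
  if (rp$dur_range_s[1] < 0.038 || rp$dur_range_s[2] > 0.5)
    stop("ripple durations must lie within [0.038, 0.5] s")
  if (sp$freq_hz < 12 || sp$freq_hz > 16)
    stop("spindle frequency must lie within [12, 16] Hz")
  if (rp$freq_hz < 80 || rp$freq_hz > 120)
    stop("ripple frequency must lie within [80, 120] Hz")
  if (cfg$fs <= 2 * max(rp$freq_hz, cfg$background$transient$band_hz[2],
                        cfg$artifact_injection$hf_freq_hz))
    stop("sampling rate must exceed twice the highest injected frequency")
  if (cp$p_couple < 0 || cp$p_couple > 1)
    stop("p_couple must be a probability in [0, 1]")
  if (cp$direction_mix < 0 || cp$direction_mix > 1)
    stop("direction_mix must lie in [0, 1]")
  invisible(cfg)
}

# Default hypnogram: wake onset, first S2 block, SWS, REM, final S2 block.
default_hypnogram <- function(duration_s, epoch_len_s = 20) {
  n_ep <- ceiling(duration_s / epoch_len_s)
  if (n_ep < 5) return(new_hypnogram(rep("S2", n_ep), epoch_len_s))
  n_w <- max(1, round(0.03 * n_ep))
  n_rem <- max(1, round(0.15 * n_ep))
  n_sws <- round(0.27 * n_ep)
  left <- n_ep - n_w - n_rem - n_sws
  n_s2a <- ceiling(left / 2)
  n_s2b <- left - n_s2a
  new_hypnogram(c(rep("W", n_w), rep("S2", n_s2a), rep("SWS", n_sws),
                  rep("REM", n_rem), rep("S2", n_s2b)), epoch_len_s)
}

pink_noise <- function(n, exponent, fs) {
  m <- nextpow2(n)
  f <- c(1, seq_len(m - 1))                 # avoid DC singularity
  f <- pmin(f, m - f) / m * fs
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  z <- stats::fft(stats::rnorm(m)) * shape
  x <- Re(stats::fft(z, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

hann_env <- function(k) 0.5 * (1 - cos(2 * pi * (seq_len(k) - 1) / max(k - 1, 1)))

# Dead-time Poisson placement inside [0, block_len]; returns event start
# times. Rate is compensated for the dead time so the realised density
# matches the nominal rate.
place_poisson <- function(block_len, rate_per_s, dead_time) {
  if (rate_per_s <= 0 || block_len <= 0) return(numeric())
  comp <- rate_per_s / max(1 - rate_per_s * dead_time, 0.2)
  out <- numeric()
  t <- stats::rexp(1, comp)
  while (t < block_len) {
    out <- c(out, t)
    t <- t + dead_time + stats::rexp(1, comp)
  }
  out
}

# Eroded NREM blocks in seconds: data.frame(start_s, end_s).
nrem_blocks <- function(nrem, fs, margin_s) {
  iv <- runs_true(nrem)
  if (nrow(iv) == 0) return(data.frame(start_s = numeric(), end_s = numeric()))
  st <- (iv[, 1] - 1) / fs + margin_s
  en <- iv[, 2] / fs - margin_s
  keep <- en > st
  data.frame(start_s = st[keep], end_s = en[keep])
}

#' Generate a synthetic two-channel sleep recording with ground truth
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (an `eeg_recording` with channels
#'   NC and HIPP), `truth` (class `ground_truth`: `events` table,
#'   `artifact_intervals`, `coupling_pairs`), and `hypnogram`.
#' @export
generate_recording <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  hyp <- if (is.null(config$hypnogram)) default_hypnogram(config$duration_s)
         else config$hypnogram
  nrem <- nrem_mask(hyp, fs, n)
  bg <- config$background

  # --- background ----------------------------------------------------------
  sig <- matrix(0, n, 2, dimnames = list(NULL, c("NC", "HIPP")))
  gain <- NULL
  for (ch in 1:2) {
    noise <- bg$rms_uv * pink_noise(n, bg$pink_exponent, fs)
    if (bg$white_rms_uv > 0)
      noise <- noise + stats::rnorm(n, sd = bg$white_rms_uv)
    if (bg$mod_depth > 0) {
      lf <- bandpass_filter(stats::rnorm(n), fs, low = NULL, high = bg$mod_freq)
      lf <- lf / max(stats::sd(lf), 1e-12)
      g <- 1 + bg$mod_depth * tanh(lf)
      noise <- noise * g
    }
    sig[, ch] <- noise
  }
  # hippocampal broadband high-frequency floor
  hf <- bg$hf_noise
  if (!is.null(hf) && hf$rms_uv > 0) {
    gb <- bandpass_filter(stats::rnorm(n), fs, hf$band_hz[1], hf$band_hz[2])
    sig[, 2] <- sig[, 2] + hf$rms_uv * gb / stats::sd(gb)
  }
  if (bg$so_amp_uv > 0) {
    so_gate <- moving_mean(as.numeric(nrem), round(4 * fs))
    tt <- (seq_len(n) - 1) / fs
    so <- bg$so_amp_uv * sin(2 * pi * bg$so_freq * tt +
                             stats::runif(1, 0, 2 * pi)) * so_gate
    sig[, 1] <- sig[, 1] + so
    sig[, 2] <- sig[, 2] + 0.7 * so
  }

  events <- empty_events()
  coupling_pairs <- data.frame(ripple_id = integer(), nc_spindle_id = integer(),
                               hipp_spindle_id = integer())
  next_id <- 1L
  blocks <- nrem_blocks(nrem, fs, margin_s = 2.5)
  avail_s <- sum(blocks$end_s - blocks$start_s)

  rp <- config$ripple_model; sp <- config$spindle_model; cp <- config$coupling
  check_capacity <- function(rate, label) {
    if (rate > 0 && avail_s < 60 / rate + 5)
      stop(sprintf(
        "recording too short to place %s events at %.2f/min: only %.1f s of usable NREM",
        label, rate, avail_s))
  }
  check_capacity(rp$rate_per_min, "ripple")
  check_capacity(sp$rate_per_min, "spindle")

  add_wave <- function(ch, start_sample, wave) {
    idx <- start_sample + seq_along(wave) - 1L
    ok <- idx >= 1L & idx <= n
    sig[idx[ok], ch] <<- sig[idx[ok], ch] + wave[ok]
  }

  make_event <- function(channel, kind, onset_s, dur_s, peak_s, amp) {
    ev <- data.frame(id = next_id, channel = channel, kind = kind,
                     onset_s = onset_s, offset_s = onset_s + dur_s,
                     peak_s = peak_s, duration_s = dur_s, peak_amp_uv = amp,
                     stringsAsFactors = FALSE)
    next_id <<- next_id + 1L
    events <<- rbind(events, ev)
    ev$id
  }

  # --- ripples (HIPP) ------------------------------------------------------
  rip_peaks <- numeric(); rip_durs <- numeric()
  if (rp$rate_per_min > 0) {
    dead <- rp$min_gap_s + mean(rp$dur_range_s)
    for (b in seq_len(nrow(blocks))) {
      ts <- place_poisson(blocks$end_s[b] - blocks$start_s[b],
                          rp$rate_per_min / 60, dead)
      rip_peaks <- c(rip_peaks, blocks$start_s[b] + ts)
    }
    rip_durs <- stats::runif(length(rip_peaks), rp$dur_range_s[1], rp$dur_range_s[2])
  }
  rip_ids <- integer(length(rip_peaks))
  med_dur <- if (length(rip_durs)) stats::median(rip_durs) else NA
  for (i in seq_along(rip_peaks)) {
    pk <- rip_peaks[i]; d <- rip_durs[i]
    amp <- rp$amp_uv * stats::rlnorm(1, 0, rp$amp_sdlog)
    k <- round(d * fs)
    trel <- (seq_len(k) - (k + 1) / 2) / fs
    env <- exp(-trel^2 / (2 * (d / 6)^2))
    wave <- amp * env * cos(2 * pi * rp$freq_hz * trel)
    # one sharp-wave cycle: negative half-wave then positive rebound
    Tsw <- 1 / rp$sharpwave_freq_hz
    ksw <- round(Tsw * fs)
    u <- (seq_len(ksw) - 1) / fs
    sw <- -rp$sharpwave_amp_uv * sin(2 * pi * u / Tsw)
    start <- round((pk - d / 2) * fs) + 1L
    add_wave(2L, start, wave)
    add_wave(2L, round((pk - Tsw / 2) * fs) + 1L, sw)
    rip_ids[i] <- make_event("HIPP", "ripple", pk - d / 2, d, pk, amp)
  }

  # --- coupled spindles ----------------------------------------------------
  trunc_norm <- function(sd) if (sd > 0) max(-3 * sd, min(3 * sd, stats::rnorm(1, 0, sd))) else 0
  coupled_sp <- list()     # per channel: matrix of (onset, offset)
  for (i in seq_along(rip_peaks)) {
    if (stats::runif(1) >= cp$p_couple) {
      coupling_pairs <- rbind(coupling_pairs,
        data.frame(ripple_id = rip_ids[i], nc_spindle_id = NA_integer_,
                   hipp_spindle_id = NA_integer_))
      next
    }
    pk <- rip_peaks[i]
    dmul <- if (config$duration_effect != 0)
      1 + config$duration_effect * (rip_durs[i] - med_dur) / med_dur else 1
    amp <- sp$amp_uv * stats::rlnorm(1, 0, sp$amp_sdlog) * max(dmul, 0.1)
    dur <- stats::runif(1, max(sp$dur_range_s[1], cp$lag_nc_s + 0.25),
                        sp$dur_range_s[2])
    on_nc <- pk - cp$lag_nc_s + trunc_norm(cp$jitter_s)
    on_h  <- pk - cp$lag_hipp_s + trunc_norm(cp$jitter_s)
    phi <- stats::runif(1, 0, 2 * pi)
    phi2 <- stats::runif(1, 0, 2 * pi)
    k <- round(dur * fs)
    env <- hann_env(k)
    t_nc <- on_nc + (seq_len(k) - 1) / fs
    w_nc <- amp * env * sin(2 * pi * sp$freq_hz * t_nc + phi)
    t_h <- on_h + (seq_len(k) - 1) / fs
    mix <- cp$direction_mix
    carrier <- mix * sin(2 * pi * sp$freq_hz * (t_h - cp$direction_delay_s) + phi) +
      (1 - mix) * sin(2 * pi * sp$freq_hz * t_h + phi2)
    nrm <- sqrt(mix^2 + (1 - mix)^2)
    w_h <- amp * env * carrier / max(nrm, 1e-9)
    add_wave(1L, round(on_nc * fs) + 1L, w_nc)
    add_wave(2L, round(on_h * fs) + 1L, w_h)
    id_nc <- make_event("NC", "spindle", on_nc, dur, on_nc + dur / 2, amp)
    id_h <- make_event("HIPP", "spindle", on_h, dur, on_h + dur / 2, amp)
    coupling_pairs <- rbind(coupling_pairs,
      data.frame(ripple_id = rip_ids[i], nc_spindle_id = id_nc,
                 hipp_spindle_id = id_h))
    coupled_sp$NC <- rbind(coupled_sp$NC, c(on_nc, on_nc + dur))
    coupled_sp$HIPP <- rbind(coupled_sp$HIPP, c(on_h, on_h + dur))
  }

  # --- uncoupled spindles --------------------------------------------------
  if (sp$rate_per_min > 0) {
    dead <- 1 + mean(sp$dur_range_s)
    for (ch in c("NC", "HIPP")) {
      ons <- numeric()
      for (b in seq_len(nrow(blocks))) {
        ts <- place_poisson(blocks$end_s[b] - blocks$start_s[b],
                            sp$rate_per_min / 60, dead)
        ons <- c(ons, blocks$start_s[b] + ts)
      }
      durs <- stats::runif(length(ons), sp$dur_range_s[1], sp$dur_range_s[2])
      # drop background spindles closer than 1 s to a coupled spindle
      if (!is.null(coupled_sp[[ch]]) && length(ons)) {
        keep <- vapply(seq_along(ons), function(i) {
          all(ons[i] + durs[i] < coupled_sp[[ch]][, 1] - 1 |
              ons[i] > coupled_sp[[ch]][, 2] + 1)
        }, TRUE)
        ons <- ons[keep]; durs <- durs[keep]
      }
      chi <- if (ch == "NC") 1L else 2L
      for (i in seq_along(ons)) {
        amp <- sp$amp_uv * stats::rlnorm(1, 0, sp$amp_sdlog)
        k <- round(durs[i] * fs)
        tt <- ons[i] + (seq_len(k) - 1) / fs
        w <- amp * hann_env(k) * sin(2 * pi * sp$freq_hz * tt +
                                     stats::runif(1, 0, 2 * pi))
        add_wave(chi, round(ons[i] * fs) + 1L, w)
        make_event(ch, "spindle", ons[i], durs[i], ons[i] + durs[i] / 2, amp)
      }
    }
  }

  # --- broadband transients (not ground-truth events) ----------------------
  tr <- bg$transient
  if (tr$rate_per_min > 0) {
    ev_spans <- cbind(events$onset_s - 1, events$offset_s + 1)
    for (ch in 1:2) {
      ons <- numeric()
      for (b in seq_len(nrow(blocks))) {
        ts <- place_poisson(blocks$end_s[b] - blocks$start_s[b],
                            tr$rate_per_min / 60, 1)
        ons <- c(ons, blocks$start_s[b] + ts)
      }
      for (o in ons) {
        d <- stats::runif(1, tr$dur_range_s[1], tr$dur_range_s[2])
        if (nrow(ev_spans) && any(o < ev_spans[, 2] & o + d > ev_spans[, 1]))
          next
        k <- round(d * fs)
        burst <- stats::rnorm(k + 200)
        burst <- bandpass_filter(burst, fs, tr$band_hz[1], tr$band_hz[2])
        burst <- burst[100 + seq_len(k)] / stats::sd(burst)
        w <- tr$amp_uv * stats::rlnorm(1, 0, 0.3) * hann_env(k) * burst
        add_wave(ch, round(o * fs) + 1L, w)
      }
    }
  }

  # hippocampal interictal-like spikes: sharp biphasic broadband transients.
  # Their filter ringing inflates ripple-band RMS statistics (as interictal
  # discharges do in patient data); the raw-cycle and frequency-profile
  # criteria of the ripple detector are what reject them downstream.
  sk <- bg$spikes
  if (!is.null(sk) && sk$rate_per_min > 0) {
    ev_spans <- cbind(events$onset_s - 0.5, events$offset_s + 0.5)
    ons <- numeric()
    for (b in seq_len(nrow(blocks))) {
      ts <- place_poisson(blocks$end_s[b] - blocks$start_s[b],
                          sk$rate_per_min / 60, 0.3)
      ons <- c(ons, blocks$start_s[b] + ts)
    }
    w <- sk$width_s
    tt <- seq(-4 * w, 4 * w, by = 1 / fs)
    shape <- -tt / w * exp(-tt^2 / (2 * w^2))
    shape <- shape / max(abs(shape))
    for (o in ons) {
      if (nrow(ev_spans) && any(o < ev_spans[, 2] & o > ev_spans[, 1]))
        next
      a <- sk$amp_uv * stats::rlnorm(1, 0, sk$amp_sdlog)
      add_wave(2L, round(o * fs) + 1L - length(tt) %/% 2L, a * shape)
    }
  }

  rec <- new_recording(sig, fs, c("NC", "HIPP"),
                       c(NC = "NC", HIPP = "HIPP"))

  # --- artifacts -----------------------------------------------------------
  art <- data.frame(start_sample = integer(), end_sample = integer(),
                    class = character())
  ai <- config$artifact_injection
  if ((ai$n_amplitude + ai$n_gradient + ai$n_hf) > 0) {
    inj <- inject_artifacts(rec, ai, seed = derive_seed(config$seed, 1),
                            nrem = nrem, avoid = cbind(events$onset_s - 2,
                                                       events$offset_s + 2))
    rec <- inj$recording
    art <- inj$intervals
  }

  truth <- structure(list(events = validate_events(events),
                          artifact_intervals = art,
                          coupling_pairs = coupling_pairs,
                          config = config),
                     class = "ground_truth")
  list(recording = rec, truth = truth, hypnogram = hyp)
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds, at ground-truth-recorded positions on both channels: boxcar
#' amplitude excursions (> 750 uV), single-sample step discontinuities with
#' exponential decay, and >150 Hz noise bursts of at least 100 ms.
#'
#' @param recording an `eeg_recording`.
#' @param config artifact-injection settings (see [sim_config()]).
#' @param seed integer seed for placement.
#' @param nrem optional logical mask restricting placement to NREM.
#' @param avoid optional 2-column matrix of time spans (s) to keep clear of.
#' @return list with the modified `recording` and the ground-truth
#'   `intervals` (`start_sample`, `end_sample`, `class`).
#' @export
inject_artifacts <- function(recording, config, seed = 1L, nrem = NULL,
                             avoid = NULL) {
  if (n_samples(recording) == 0) stop("empty recording")
  set.seed(as.integer(seed %% 2147483647))
  fs <- recording$fs
  n <- n_samples(recording)
  sig <- recording$signals
  iv <- data.frame(start_sample = integer(), end_sample = integer(),
                   class = character())
  allowed <- if (is.null(nrem)) rep(TRUE, n) else nrem
  place_one <- function(dur_samples) {
    for (try in 1:500) {
      s <- sample.int(n - dur_samples - 1L, 1)
      e <- s + dur_samples - 1L
      if (!all(allowed[s:e])) next
      span_s <- c((s - 1) / fs, e / fs)
      if (!is.null(avoid) && nrow(avoid) &&
          any(span_s[1] < avoid[, 2] & span_s[2] > avoid[, 1])) next
      if (nrow(iv) && any(s <= iv$end_sample + fs & e >= iv$start_sample - fs)) next
      return(c(s, e))
    }
    stop("cannot place requested artifacts without overlap; reduce counts")
  }
  total <- config$n_amplitude + config$n_gradient + config$n_hf
  if (total == 0) return(list(recording = recording, intervals = iv))
  for (i in seq_len(config$n_amplitude)) {
    k <- round(config$amp_dur_s * fs)
    se <- place_one(k)
    sig[se[1]:se[2], ] <- sig[se[1]:se[2], ] + config$amplitude_uv
    iv <- rbind(iv, data.frame(start_sample = se[1], end_sample = se[2],
                               class = "amplitude"))
  }
  for (i in seq_len(config$n_gradient)) {
    k <- round(0.25 * fs)
    se <- place_one(k)
    decay <- config$step_uv * exp(-(seq_len(k) - 1) / (0.05 * fs))
    sig[se[1]:se[2], ] <- sig[se[1]:se[2], ] + decay
    iv <- rbind(iv, data.frame(start_sample = se[1], end_sample = se[1],
                               class = "gradient"))
  }
  for (i in seq_len(config$n_hf)) {
    k <- round(config$hf_dur_s * fs)
    se <- place_one(k)
    tt <- (seq_len(k) - 1) / fs
    # flat envelope with 10 ms cosine ramps: the supra-threshold run tracks
    # the physical burst duration
    ramp <- round(0.01 * fs)
    env <- rep(1, k)
    env[seq_len(ramp)] <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[k + 1 - seq_len(ramp)] <- env[seq_len(ramp)]
    burst <- config$hf_amp_uv * env * sin(2 * pi * config$hf_freq_hz * tt)
    sig[se[1]:se[2], ] <- sig[se[1]:se[2], ] + burst
    iv <- rbind(iv, data.frame(start_sample = se[1], end_sample = se[2],
                               class = "hf_burst"))
  }
  rec <- new_recording(sig, fs, recording$channel_names, recording$roles)
  list(recording = rec, intervals = iv)
}

#' Canonical "coupling night" configuration
#'
#' A longer synthetic night with ripple density close to patient data
#' (about 2 events per minute), used for the surrogate-control and
#' connectivity analyses: drawing 100 non-overlapping control sets requires
#' the ripple-core occupancy of the clean NREM pool to stay low, which the
#' denser detector-validation phantom (the [sim_config()] default, chosen
#' for threshold stability) does not satisfy on a short night.
#'
#' @param seed integer seed.
#' @param duration_s night length in seconds (45 min).
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_coupling <- function(seed = 1L, duration_s = 2700, ...) {
  sim_config(duration_s = duration_s, seed = seed,
             ripple_model = list(rate_per_min = 2.2,
                                 dur_range_s = c(0.10, 0.22)),
             ...)
}

#' Write a simulated night to disk
#'
#' Writes the recording (EDF by default), the hypnogram as plain text, the
#' ground-truth event table as TSV, and a JSON sidecar with coupling pairs
#' and artifact intervals.
#'
#' @param sim result of [generate_recording()].
#' @param dir output directory (created if missing).
#' @param format recording format, `"edf"` or `"raw"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = "edf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "edf") "edf" else "bin"
  write_recording(sim$recording, file.path(dir, paste0("recording.", ext)),
                  format)
  write_hypnogram(sim$hypnogram, file.path(dir, "hypnogram.txt"))
  write_events(sim$truth$events, file.path(dir, "truth_events.tsv"))
  jsonlite::write_json(
    list(coupling_pairs = sim$truth$coupling_pairs,
         artifact_intervals = sim$truth$artifact_intervals),
    file.path(dir, "truth_sidecar.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
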