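# Shared fixtures: small simulation configs and a quiet background config
# with every stochastic component switched off except pink noise.

quiet_background <- function(...) {
  utils::modifyList(list(
    white_rms_uv = 0, so_amp_uv = 0, mod_depth = 0,
    transient = list(rate_per_min = 0, amp_uv = 0,
                     dur_range_s = c(0.05, 0.2), band_hz = c(25, 70)),
    hf_noise = list(rms_uv = 0, band_hz = c(60, 250)),
    spikes = list(rate_per_min = 0, amp_uv = 0, amp_sdlog = 0.25,
                  width_s = 0.003)), list(...))
}

no_event_config <- function(duration_s = 120, seed = 1,
                            background = quiet_background(), ...) {
  sim_config(duration_s = duration_s, seed = seed,
             background = background,
             spindle_model = list(rate_per_min = 0),
             ripple_model = list(rate_per_min = 0),
             ...)
}

# tiny two-channel recording built from deterministic waveforms
toy_recording <- function(n = 5000, fs = 1000) {
  tt <- (seq_len(n) - 1) / fs
  new_recording(cbind(NC = 20 * sin(2 * pi * 10 * tt),
                      HIPP = 10 * sin(2 * pi * 6 * tt)),
                fs, c("NC", "HIPP"), c(NC = "NC", HIPP = "HIPP"))
}

# complex TFR-like stack with given dims filled from a function(ev, f, t)
fake_tfr <- function(nev, freq_hz, time_s, fill) {
  co <- array(0i, c(nev, length(freq_hz), length(time_s)))
  for (e in seq_len(nev))
    for (k in seq_along(freq_hz))
      co[e, k, ] <- fill(e, freq_hz[k], time_s)
  structure(list(coeffs = co, freq_hz = freq_hz, time_s = time_s,
                 valid = matrix(TRUE, length(freq_hz), length(time_s)),
                 lock = "test"),
            class = "tfr_stack")
}

iv_mask <- function(iv, n) ripplelock:::intervals_to_mask(iv, n)
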