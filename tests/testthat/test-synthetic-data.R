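test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(duration_s = 60, seed = 11)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_identical(a$truth$events, b$truth$events)
  c2 <- generate_recording(sim_config(duration_s = 60, seed = 12))
  expect_false(identical(a$recording$signals, c2$recording$signals))
})

test_that("zero event rates give an empty ground truth", {
  sim <- generate_recording(no_event_config())
  expect_equal(nrow(sim$truth$events), 0)
  expect_equal(nrow(sim$truth$artifact_intervals), 0)
})

test_that("all coupled spindle onsets precede their ripple peak by the configured lag", {
  cfg <- sim_config(duration_s = 600, seed = 3,
                    ripple_model = list(rate_per_min = 1),
                    coupling = list(p_couple = 1, jitter_s = 0.015))
  sim <- generate_recording(cfg)
  ev <- sim$truth$events
  cp <- sim$truth$coupling_pairs
  rip <- ev[ev$kind == "ripple", ]
  expect_gt(nrow(rip), 3)
  expect_true(all(rip$id %in% cp$ripple_id))
  expect_false(any(is.na(cp$nc_spindle_id)))
  for (i in seq_len(nrow(cp))) {
    pk <- ev$peak_s[ev$id == cp$ripple_id[i]]
    lag_nc <- pk - ev$onset_s[ev$id == cp$nc_spindle_id[i]]
    lag_hipp <- pk - ev$onset_s[ev$id == cp$hipp_spindle_id[i]]
    expect_lt(abs(lag_nc - 0.225), 3 * 0.015 + 1e-9)
    expect_lt(abs(lag_hipp - 0.075), 3 * 0.015 + 1e-9)
  }
})

test_that("ground truth closure: events lie inside the recording within stated duration ranges", {
  cfg <- sim_config(duration_s = 300, seed = 8,
                    artifact_injection = list(n_amplitude = 1, n_gradient = 1,
                                              n_hf = 1))
  sim <- generate_recording(cfg)
  ev <- sim$truth$events
  expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 300))
  sp <- ev[ev$kind == "spindle", ]
  rp <- ev[ev$kind == "ripple", ]
  expect_true(all(sp$duration_s >= 0.4 & sp$duration_s <= 3))
  expect_true(all(rp$duration_s >= 0.038 & rp$duration_s <= 0.5))
  expect_true(all(ev$onset_s < ev$peak_s & ev$peak_s <= ev$offset_s))
  ai <- sim$truth$artifact_intervals
  expect_true(all(ai$start_sample >= 1 & ai$end_sample <= 300 * 1000))
})

test_that("background pink noise follows the configured 1/f slope", {
  for (expo in c(1, 1.5)) {
    cfg <- no_event_config(duration_s = 240, seed = 21,
                           background = quiet_background(pink_exponent = expo))
    sim <- generate_recording(cfg)
    x <- sim$recording$signals[, "NC"]
    sp <- spec.pgram(ts(x, frequency = 1000), spans = 31, plot = FALSE,
                     taper = 0.1)
    sel <- sp$freq > 1 & sp$freq < 100
    fit <- lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
    expect_lt(abs(unname(coef(fit)[2]) + expo), 0.15)
  }
})

test_that("NC->HIPP coupling delay is recoverable by band-limited cross-correlation", {
  # pure delayed-copy configuration: equal durations, no jitter, mix = 1
  cfg <- sim_config(duration_s = 600, seed = 5,
                    background = quiet_background(white_rms_uv = 4),
                    spindle_model = list(rate_per_min = 0),
                    ripple_model = list(rate_per_min = 1.5),
                    coupling = list(p_couple = 1, jitter_s = 0,
                                    lag_nc_s = 0.225, lag_hipp_s = 0.205,
                                    direction_delay_s = 0.02,
                                    direction_mix = 1))
  sim <- generate_recording(cfg)
  fs <- 1000
  nc <- bandpass_filter(sim$recording$signals[, "NC"], fs, 12, 16)
  hp <- bandpass_filter(sim$recording$signals[, "HIPP"], fs, 12, 16)
  ev <- sim$truth$events
  rip <- ev[ev$kind == "ripple", ]
  # narrowband signals identify the delay modulo the carrier period; search
  # within half a period to resolve the comb ambiguity
  lags <- -36:36
  best <- vapply(rip$peak_s, function(pk) {
    c0 <- round(pk * fs)
    win <- (c0 - 500):(c0 + 500)
    cc <- vapply(lags, function(l) cor(nc[win], hp[win + l]), 0)
    lags[which.max(cc)]
  }, 0)
  # delay = 20 ms -> +20 samples (placement discretizes each onset by
  # up to half a sample; band-pass ringing can add another)
  expect_true(all(abs(best - 20) <= 3))
  expect_lte(abs(median(best) - 20), 1)
})

test_that("injected artifacts match their ground-truth positions", {
  rec <- toy_recording(n = 60000)
  out0 <- inject_artifacts(rec, list(n_amplitude = 0, n_gradient = 0,
                                     n_hf = 0), seed = 1)
  expect_identical(out0$recording$signals, rec$signals)

  cfgA <- list(n_amplitude = 1, n_gradient = 0, n_hf = 0,
               amplitude_uv = 900, amp_dur_s = 0.3, step_uv = 400,
               hf_amp_uv = 60, hf_freq_hz = 200, hf_dur_s = 0.15)
  outA <- inject_artifacts(rec, cfgA, seed = 2)
  iv <- outA$intervals
  expect_equal(iv$class, "amplitude")
  seg <- outA$recording$signals[iv$start_sample:iv$end_sample, 1]
  expect_gte(max(abs(seg)), 750)

  cfgG <- utils::modifyList(cfgA, list(n_amplitude = 0, n_gradient = 1,
                                       step_uv = 2000))
  outG <- inject_artifacts(rec, cfgG, seed = 3)
  ivg <- outG$intervals
  expect_equal(ivg$class, "gradient")
  k <- ivg$start_sample
  jump <- outG$recording$signals[k, 1] - outG$recording$signals[k - 1, 1] -
    (rec$signals[k, 1] - rec$signals[k - 1, 1])
  expect_equal(unname(jump), 2000, tolerance = 1e-6)
})
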