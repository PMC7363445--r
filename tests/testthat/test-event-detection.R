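test_that("rms_envelope matches a brute-force two-pass definition", {
  fs <- 100
  expect_equal(rms_envelope(rep(3, 200), fs), rep(3, 200))
  expect_equal(rms_envelope(rep(-2.5, 200), fs), rep(2.5, 200))

  tt <- (0:999) / 1000
  s <- 4 * sin(2 * pi * 20 * tt)            # window 200 ms = 4 periods
  env <- rms_envelope(s, 1000, 0.2, 0.2)
  expect_lt(max(abs(env[300:700] - 4 / sqrt(2))), 0.01 * 4 / sqrt(2))

  set.seed(9)
  x <- rnorm(50)
  got <- rms_envelope(x, fs = 10, window_s = 0.5, smooth_s = 0.5)
  # oracle: centered moving RMS then centered moving average, shrinking edges
  w <- 5; h <- 2
  r1 <- sapply(seq_along(x), function(i) {
    idx <- max(1, i - h):min(length(x), i + h)
    sqrt(mean(x[idx]^2))
  })
  oracle <- sapply(seq_along(x), function(i) {
    idx <- max(1, i - h):min(length(x), i + h)
    mean(r1[idx])
  })
  expect_equal(got, oracle)
  expect_error(rms_envelope(numeric(0), 100), "empty")
})

test_that("count_raw_cycles counts alternating qualifying half-waves", {
  fs <- 1000
  tt <- (0:999) / fs
  sine <- sin(2 * pi * 90 * tt)
  expect_equal(count_raw_cycles(sine, fs, 0.2, 0.25,
                                prefiltered = sine), 4L)  # floor(0.05 * 90)
  expect_equal(count_raw_cycles(numeric(1000), fs, 0.1, 0.3,
                                prefiltered = numeric(1000)), 0L)
  # three-cycle constant-amplitude burst: six qualifying half-waves
  dur <- 3 / 90
  k <- round(dur * fs)
  burst <- numeric(1000)
  burst[501:(500 + k)] <- sin(2 * pi * 90 * (0:(k - 1)) / fs)
  expect_equal(count_raw_cycles(burst, fs, 0.5, 0.5 + dur,
                                prefiltered = burst), 3L)
})

test_that("detection recovers injected spindles to within 100 ms", {
  fs <- 1000
  set.seed(10)
  n <- 120 * fs
  x <- bandpass_filter(rnorm(n, sd = 30), fs, 5, 30)  # band-limited background
  b <- sd(bandpass_filter(x, fs, 12, 16))
  ons <- seq(10, 110, by = 10)
  k <- fs                                   # 1 s, 13 Hz, 5x band background
  for (o in ons) {
    idx <- (o * fs):(o * fs + k - 1)
    x[idx] <- x[idx] + 5 * b * sqrt(2) * sin(2 * pi * 13 * (0:(k - 1)) / fs)
  }
  p <- detector_params("spindle", upper_sd = 50)
  ev <- detect_events(x, fs, rep(FALSE, n), rep(TRUE, n), p, "NC")
  expect_equal(nrow(ev), length(ons))
  expect_true(all(ev$kind == "spindle"))
  for (o in ons) {
    expect_lt(min(abs(ev$onset_s - o)), 0.1)
    expect_lt(min(abs(ev$offset_s - o - 1)), 0.1)
  }

  # envelope never crossing the threshold yields an empty table
  flat <- sin(2 * pi * 5 * (0:(20 * fs - 1)) / fs)
  ev0 <- detect_events(flat, fs, rep(FALSE, 20 * fs), rep(TRUE, 20 * fs),
                       detector_params("spindle"), "NC")
  expect_equal(nrow(ev0), 0)
  expect_error(detect_events(flat, fs, rep(TRUE, 20 * fs),
                             rep(TRUE, 20 * fs),
                             detector_params("spindle"), "NC"),
               "NREM")
})

test_that("sub-38 ms bursts are rejected by the ripple duration bound", {
  fs <- 1000
  set.seed(11)
  n <- 60 * fs
  x <- rnorm(n, sd = 3)
  tt <- (0:(n - 1)) / fs
  k <- 30                                    # 30 ms, below 3 cycles at 80 Hz
  on <- 30 * fs
  x[on:(on + k - 1)] <- x[on:(on + k - 1)] +
    40 * sin(2 * pi * 90 * (0:(k - 1)) / fs)
  ev <- detect_events(x, fs, rep(FALSE, n), rep(TRUE, n),
                      detector_params("ripple"), "HIPP")
  hits <- ev[abs(ev$peak_s - 30) < 0.2, ]
  expect_equal(nrow(hits), 0)
})

test_that("detected events are invariant to positive rescaling of the signal", {
  cfg <- sim_config(duration_s = 240, seed = 14)
  sim <- generate_recording(cfg)
  fs <- 1000
  nrem <- nrem_mask(sim$hypnogram, fs, nrow(sim$recording$signals))
  mask <- rep(FALSE, length(nrem))
  x <- sim$recording$signals[, "HIPP"]
  p <- detector_params("ripple")
  a <- detect_events(x, fs, mask, nrem, p, "HIPP")
  b <- detect_events(3.7 * x, fs, mask, nrem, p, "HIPP")
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$offset_s, b$offset_s)
  expect_equal(a$peak_s, b$peak_s)
})

test_that("frequency profile separates narrowband events from broadband transients", {
  fs <- 1000
  set.seed(12)
  n <- 20 * fs
  base <- rnorm(n, sd = 2)
  p <- detector_params("spindle")

  narrow <- base
  k <- fs
  narrow[9501:(9500 + k)] <- narrow[9501:(9500 + k)] +
    20 * ripplelock:::hann_env(k) * sin(2 * pi * 13 * (0:(k - 1)) / fs)
  expect_true(frequency_profile_ok(narrow, fs, 10, p))

  # broadband impulse transient: flat spectrum, the 9-19 Hz profile has its
  # maximum below the 12-16 Hz band of interest
  broad <- base
  broad[10001] <- broad[10001] + 500
  expect_false(isTRUE(frequency_profile_ok(broad, fs, 10, p)))

  # strictly monotonic profile (pure low-frequency content)
  mono <- 30 * sin(2 * pi * 5 * (0:(n - 1)) / fs)
  expect_false(isTRUE(frequency_profile_ok(mono, fs, 10, p)))

  # event too close to the recording edge is rejected with a reason
  near_edge <- frequency_profile_ok(narrow, fs, 0.2, p)
  expect_false(isTRUE(near_edge))
  expect_equal(attr(near_edge, "reason"), "edge")
})

test_that("event density is count per clean-NREM minute", {
  ev <- empty_events()
  expect_equal(event_density(ev, 600), 0)
  ev10 <- do.call(rbind, replicate(10, {
    data.frame(id = 1, channel = "NC", kind = "spindle", onset_s = 1,
               offset_s = 2, peak_s = 1.5, duration_s = 1, peak_amp_uv = 1)
  }, simplify = FALSE))
  expect_equal(event_density(ev10, 600), 1)
  expect_error(event_density(ev10, 0), "positive")
})
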