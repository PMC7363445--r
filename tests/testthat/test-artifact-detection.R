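test_that("amplitude detector flags exactly the supra-threshold excursions", {
  fs <- 1000
  x <- numeric(10 * fs)
  x[3000:3999] <- 800                       # 800 uV boxcar: onset exceeds 750
  iv <- detect_amplitude_artifacts(x, fs)
  expect_gte(nrow(iv), 1)
  m <- iv_mask(iv, length(x))
  expect_true(any(m[2990:3050]))
  expect_false(any(m[1:2500]))
  # flags are exactly the threshold exceedances of the filtered trace
  oracle <- abs(ripplelock:::acquisition_filter(x, fs, 0.3, 150)) > 750
  expect_identical(m, oracle)
  expect_equal(nrow(detect_amplitude_artifacts(numeric(5000), fs)), 0)

  spike <- numeric(10 * fs); spike[5000:5004] <- 1500   # 5 ms pop
  ivs <- detect_amplitude_artifacts(spike, fs)
  ms <- iv_mask(ivs, length(spike))
  expect_true(any(ms[4995:5010]))
  expect_error(detect_amplitude_artifacts(x, 200), "fs")
})

test_that("gradient detector reproduces the median +/- 6 IQR rule", {
  fs <- 1000
  expect_equal(nrow(detect_gradient_artifacts(seq_len(5000) * 0.01, fs)), 0)

  set.seed(4)
  x <- rnorm(20000, sd = 10)
  x[8000:20000] <- x[8000:20000] + 2000     # 2000 uV step at sample 8000
  iv <- detect_gradient_artifacts(x, fs)
  m <- iv_mask(iv, length(x))
  expect_true(any(m[7995:8005]))
  # brute-force oracle on the same filtered trace
  xf <- ripplelock:::acquisition_filter(x, fs, 0.3, 150)
  d <- c(diff(xf), 0)
  thr_lo <- median(d) - 6 * IQR(d)
  thr_hi <- median(d) + 6 * IQR(d)
  oracle <- d > thr_hi | d < thr_lo
  expect_identical(m, oracle)

  # Gaussian noise: 6 IQR is ~8 SD for normal differences, flags are rare
  set.seed(5)
  g <- rnorm(50000, sd = 20)
  mg <- iv_mask(detect_gradient_artifacts(g, fs), length(g))
  expect_lt(mean(mg), 0.01)
  expect_error(detect_gradient_artifacts(c(1), fs), "2 samples")
})

test_that("high-frequency burst detector honors the 100 ms minimum duration", {
  fs <- 1000
  set.seed(6)
  base <- rnorm(30000, sd = 2)
  tt <- (seq_len(30000) - 1) / fs
  add_burst <- function(x, at, dur) {
    idx <- at:(at + dur - 1)
    x[idx] <- x[idx] + 20 * sin(2 * pi * 200 * tt[idx])
    x
  }
  x150 <- add_burst(base, 10000, 150)
  iv <- detect_hf_burst_artifacts(x150, fs)
  m <- iv_mask(iv, length(x150))
  expect_true(any(m[10000:10149]))

  x50 <- add_burst(base, 10000, 50)
  iv50 <- detect_hf_burst_artifacts(x50, fs)
  m50 <- iv_mask(iv50, length(x50))
  expect_false(any(m50[9900:10250]))

  sine <- 100 * sin(2 * pi * 10 * tt)
  expect_equal(nrow(detect_hf_burst_artifacts(sine, fs)), 0)
  expect_error(detect_hf_burst_artifacts(base, 300), "fs")
})

test_that("finalize_mask pads by 250 ms and closes clean gaps below 3 s", {
  fs <- 1000
  n <- 20 * fs
  one <- list(amplitude = cbind(start = 10001L, end = 10001L))
  m1 <- finalize_mask(one, fs, n)
  expect_true(all(m1$mask[9751:10251]))
  expect_false(m1$mask[9749])
  expect_false(m1$mask[10253])

  two_close <- list(amplitude = cbind(start = c(5000L, 7750L),
                                      end = c(5000L, 7750L)))
  m2 <- finalize_mask(two_close, fs, n)       # 2.0 s clean gap -> closed
  expect_true(all(m2$mask[4750:8000]))
  expect_gte(nrow(m2$intervals$short_gap), 1)

  two_far <- list(amplitude = cbind(start = c(5000L, 9750L),
                                    end = c(5000L, 9750L)))
  m3 <- finalize_mask(two_far, fs, n)         # 4.0 s clean gap -> kept
  expect_false(any(m3$mask[5500:9300]))
})

test_that("finalize_mask is a fixed point on its own padded intervals", {
  fs <- 500
  n <- 30 * fs
  iv <- list(amplitude = cbind(start = c(1000L, 4000L), end = c(1200L, 4100L)),
             hf_burst = cbind(start = 9000L, end = 9300L))
  m <- finalize_mask(iv, fs, n)
  again <- finalize_mask(m$intervals, fs, n, pad_s = 0)
  expect_identical(again$mask, m$mask)
})

test_that("adding artifact intervals never shrinks the final mask", {
  fs <- 500
  n <- 60 * fs
  set.seed(7)
  base <- list(amplitude = cbind(start = c(2000L, 15000L),
                                 end = c(2100L, 15050L)))
  m0 <- finalize_mask(base, fs, n)
  for (k in 1:5) {
    s <- sample.int(n - 200L, 1)
    grown <- base
    grown$gradient <- cbind(start = s, end = s + 100L)
    m1 <- finalize_mask(grown, fs, n)
    expect_true(all(m1$mask[m0$mask]))
  }
})

test_that("injected artifacts on a synthetic night are masked near-completely", {
  cfg <- sim_config(duration_s = 300, seed = 13,
                    artifact_injection = list(n_amplitude = 2, n_gradient = 2,
                                              n_hf = 2))
  sim <- generate_recording(cfg)
  art <- detect_artifacts(sim$recording, sim$hypnogram)
  iv <- sim$truth$artifact_intervals
  covered <- unlist(lapply(seq_len(nrow(iv)), function(i)
    art$combined[iv$start_sample[i]:iv$end_sample[i]]))
  expect_gte(mean(covered), 0.95)
  # clean-night budget: without injected artifacts little is masked
  clean <- generate_recording(sim_config(duration_s = 300, seed = 13))
  artc <- detect_artifacts(clean$recording, clean$hypnogram)
  expect_lt(mean(artc$combined), 0.05)
})
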