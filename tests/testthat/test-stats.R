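test_that("z against controls follows its definition and calibrates under the null", {
  ctrl <- rnorm(100, mean = 3, sd = 1)
  z0 <- z_vs_controls(mean(ctrl), ctrl)
  expect_equal(z0$value, 0, tolerance = 1e-12)
  z2 <- z_vs_controls(5, c(rep(2, 50), rep(4, 50)))
  expect_equal(z2$value, (5 - 3) / sd(c(rep(2, 50), rep(4, 50))),
               tolerance = 1e-12)
  expect_error(z_vs_controls(1, rep(2, 100)), "spread")

  set.seed(60)
  hits <- replicate(800, {
    ctrl <- rnorm(100); emp <- rnorm(1)
    abs(z_vs_controls(emp, ctrl)$value) > 1.96
  })
  # nominal ~5%, slightly above because control moments are estimated
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.10)
})

test_that("cluster permutation finds an injected rectangle and nothing in silence", {
  set.seed(61)
  n <- 20; nf <- 20; nt <- 30
  ev <- array(rnorm(n * nf * nt), c(n, nf, nt))
  ct <- array(rnorm(n * nf * nt), c(n, nf, nt))
  rect_f <- 5:10; rect_t <- 10:17
  ev[, rect_f, rect_t] <- ev[, rect_f, rect_t] + 2
  res <- cluster_permutation(ev, ct, n_perm = 300, seed = 1)
  sig <- res$clusters[res$clusters$p_corrected < 0.05 & res$clusters$mass > 0, ]
  expect_equal(nrow(sig), 1)
  inside <- res$label_map[rect_f, rect_t] == sig$id
  expect_gte(mean(inside), 0.8)

  same <- array(rnorm(n * nf * nt), c(n, nf, nt))
  none <- cluster_permutation(same, same, n_perm = 50, seed = 2)
  expect_equal(nrow(none$clusters), 0)
  expect_error(cluster_permutation(ev[1:3, , ], ct[1:3, , ]), "5 pairs")
})

test_that("cluster permutation p-values are invariant to amplitude scaling", {
  set.seed(62)
  n <- 12; nf <- 8; nt <- 10
  ev <- array(rnorm(n * nf * nt, mean = 0.4), c(n, nf, nt))
  ct <- array(rnorm(n * nf * nt), c(n, nf, nt))
  a <- cluster_permutation(ev, ct, n_perm = 200, seed = 3)
  b <- cluster_permutation(ev * 50, ct * 50, n_perm = 200, seed = 3)
  expect_equal(a$clusters$p_corrected, b$clusters$p_corrected)
  expect_equal(a$t_map, b$t_map, tolerance = 1e-9)
})

test_that("onset histograms are normalized by all spindle onsets times 100", {
  sp <- data.frame(id = 1:10, channel = "NC", kind = "spindle",
                   onset_s = c(9.96, 9.97, 30, 40, 50, 60, 70, 80, 90, 95),
                   offset_s = NA, peak_s = NA, duration_s = 1,
                   peak_amp_uv = 1)
  rp <- data.frame(id = 1, peak_s = 10, duration_s = 0.1,
                   onset_s = 9.95, offset_s = 10.05)
  h <- spindle_onset_histogram(sp, rp)
  # two onsets in the bin just before the ripple peak -> 20% of 10 onsets
  expect_equal(max(h$value), 20)
  expect_equal(h$peak_bin_s, -0.025)
  expect_equal(sum(h$counts), 2)
  # counts times total/100 recover the in-range onset count exactly
  expect_equal(sum(h$value) * nrow(sp) / 100, 2)

  far <- sp; far$onset_s <- far$onset_s + 500
  h0 <- spindle_onset_histogram(far, rp)
  expect_true(all(h0$value == 0))
  expect_error(spindle_onset_histogram(sp[0, ], rp), "spindle")
})

test_that("per-bin histogram z flags only genuinely enriched bins", {
  set.seed(63)
  sp <- data.frame(id = 1:200, channel = "NC", kind = "spindle",
                   onset_s = runif(200, 0, 1000), offset_s = NA, peak_s = NA,
                   duration_s = 1, peak_amp_uv = 1)
  rp <- data.frame(id = 1:20, peak_s = seq(25, 975, by = 50))
  sp$onset_s[1:60] <- rep(rp$peak_s, 3) - 0.22 + rnorm(60, sd = 0.01)
  ctrl <- matrix(runif(100 * 20, 0, 1000), 100, 20)
  h <- spindle_onset_histogram(sp, rp, ctrl)
  expect_equal(h$peak_bin_s, -0.225)
  expect_true(h$significant[which.max(h$value)])
  expect_lt(mean(h$significant), 0.4)
})

test_that("tertile split matches interpolated quantiles and handles ties", {
  ev <- data.frame(id = 1:9, duration_s = 1:9)
  ts <- tertile_split(ev)
  expect_equal(sort(ts$short$duration_s), c(1, 2, 3))
  expect_equal(sort(ts$long$duration_s), c(7, 8, 9))

  expect_warning(tse <- tertile_split(data.frame(id = 1:6, duration_s = rep(2, 6))),
                 "degenerate")
  expect_equal(nrow(tse$short), 0)
  expect_equal(nrow(tse$long), 0)

  set.seed(64)
  rnd <- data.frame(id = 1:90, duration_s = runif(90),
                    patient = rep(c("a", "b", "c"), each = 30))
  tr <- tertile_split(rnd)
  for (p in c("a", "b", "c")) {
    expect_lte(abs(sum(tr$short$patient == p) - 10), 1)
    expect_lte(abs(sum(tr$long$patient == p) - 10), 1)
  }
  expect_error(tertile_split(data.frame(id = 1:2, duration_s = 1:2)),
               "fewer than 3")
})

test_that("long-vs-short test is one-sided with pooled variance", {
  x <- c(1, 2, 3, 4, 5)
  r <- long_vs_short_power_test(x, x)
  expect_equal(r$p.value, 0.5, tolerance = 1e-12)
  expect_error(long_vs_short_power_test(rep(1, 5), rep(1, 5)), "degenerate")
  set.seed(65)
  calib <- replicate(400, {
    long_vs_short_power_test(rnorm(20), rnorm(20))$p.value < 0.05
  })
  expect_gt(mean(calib), 0.02)
  expect_lt(mean(calib), 0.09)
})

test_that("duration-power correlation clips perfect correlations and recovers effects", {
  perfect <- data.frame(patient = rep(c("a", "b", "c"), each = 5),
                        duration_s = rep(1:5, 3), power = rep(1:5, 3))
  r <- duration_power_correlation(perfect)
  expect_equal(r$per_patient$r, rep(1, 3))
  expect_true(is.infinite(r$t) && r$t > 0)
  expect_equal(r$p, 0)

  set.seed(66)
  eff <- do.call(rbind, lapply(1:5, function(p) {
    d <- runif(40)
    data.frame(patient = p, duration_s = d, power = d + rnorm(40, sd = 0.5))
  }))
  re <- duration_power_correlation(eff)
  expect_gt(re$mean_r, 0)
  expect_lt(re$p, 0.05)

  expect_warning(
    expect_error(duration_power_correlation(
      data.frame(patient = rep(1:3, each = 3), duration_s = 1,
                 power = rnorm(9))), "3 patients"),
    "excluded")
})

test_that("event contingency matches a brute-force double loop", {
  far_sp <- data.frame(onset_s = c(10, 20), offset_s = c(11, 21),
                       peak_s = c(10.5, 20.5))
  far_rp <- data.frame(onset_s = 100, offset_s = 100.1, peak_s = 100.05)
  expect_equal(event_contingency(far_sp, far_rp),
               list(pct_spindles_near_ripples = 0,
                    pct_ripples_with_spindle = 0))

  paired_rp <- data.frame(onset_s = c(10, 20), offset_s = c(10.1, 20.1),
                          peak_s = c(10.05, 20.05))
  paired_sp <- data.frame(onset_s = c(9.85, 19.85),
                          offset_s = c(10.85, 20.85), peak_s = c(10.3, 20.3))
  cont <- event_contingency(paired_sp, paired_rp)
  expect_equal(cont$pct_ripples_with_spindle, 100)

  set.seed(67)
  sp <- data.frame(onset_s = runif(80, 0, 500))
  sp$offset_s <- sp$onset_s + runif(80, 0.5, 1.5)
  rp <- data.frame(onset_s = runif(30, 0, 500))
  rp$offset_s <- rp$onset_s + 0.1
  rp$peak_s <- rp$onset_s + 0.05
  got <- event_contingency(sp, rp)
  near <- 0; olap <- 0
  for (i in seq_len(80)) {
    if (any(abs(sp$onset_s[i] - rp$peak_s) <= 1)) near <- near + 1
  }
  for (j in seq_len(30)) {
    if (any(sp$onset_s < rp$offset_s[j] & sp$offset_s > rp$onset_s[j]))
      olap <- olap + 1
  }
  expect_equal(got$pct_spindles_near_ripples, 100 * near / 80)
  expect_equal(got$pct_ripples_with_spindle, 100 * olap / 30)
})
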