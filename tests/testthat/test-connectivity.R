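random_stack <- function(nev, nf = 5, nt = 7, seed = 1) {
  set.seed(seed)
  fake_tfr(nev, seq_len(nf), seq_len(nt) / 10,
           function(e, f, t) complex(real = rnorm(length(t)),
                                     imaginary = rnorm(length(t))))
}

test_that("coherence limits: identity, fixed phase shift, independent noise", {
  X <- random_stack(50, seed = 20)
  expect_true(all(abs(coherence(X, X) - 1) < 1e-12))
  Y <- X; Y$coeffs <- Y$coeffs * exp(1i * 0.8)
  expect_true(all(abs(coherence(X, Y) - 1) < 1e-12))
  A <- random_stack(200, seed = 21); B <- random_stack(200, seed = 22)
  expect_lt(mean(coherence(A, B)), 0.15)
  one <- random_stack(1, seed = 23)
  expect_error(coherence(one, one), "trials")
  # global channel rescaling leaves coherence unchanged
  B2 <- B; B2$coeffs <- B2$coeffs * 17
  expect_equal(coherence(A, B2), coherence(A, B), tolerance = 1e-12)
})

test_that("PLV limits: constant lag, antiphase cancellation, uniform phases", {
  X <- random_stack(40, seed = 24)
  Y <- X; Y$coeffs <- Y$coeffs * exp(-1i * 1.1)
  expect_true(all(abs(plv(X, Y) - 1) < 1e-12))

  two <- fake_tfr(2, 1, 1, function(e, f, t) exp(1i * ifelse(e == 1, 0, pi)))
  ref <- fake_tfr(2, 1, 1, function(e, f, t) 1 + 0i)
  expect_lt(abs(plv(two, ref)[1, 1]), 1e-12)

  A <- random_stack(200, seed = 25); B <- random_stack(200, seed = 26)
  expect_lt(mean(plv(A, B)), 0.15)
  # per-trial amplitude rescaling leaves PLV unchanged
  A2 <- A; A2$coeffs <- A2$coeffs * rexp(200)
  expect_equal(plv(A2, B), plv(A, B), tolerance = 1e-10)
})

test_that("band and window means equal loop oracles", {
  set.seed(27)
  m <- matrix(rnorm(8 * 11), 8, 11)
  freq <- seq(10, 17, by = 1)
  tim <- seq(-0.5, 0.5, by = 0.1)
  bm <- band_mean(m, freq, c(12, 16))
  oracle <- sapply(seq_len(11), function(j) mean(m[freq >= 12 & freq <= 16, j]))
  expect_equal(bm, oracle)
  expect_equal(band_mean(m, freq, c(13, 13)), m[freq == 13, ])
  expect_error(band_mean(m, freq, c(30, 40)), "band")

  wm <- window_mean(m, freq, tim, c(-0.22, 0.46), c(11.5, 18))
  cells <- m[freq >= 11.5 & freq <= 18, tim >= -0.22 & tim <= 0.46]
  expect_equal(wm, mean(cells))
  expect_equal(window_mean(m, freq, tim, c(-0.5, -0.5), c(10, 10)),
               m[1, 1])
  expect_equal(window_mean(matrix(3.3, 8, 11), freq, tim), 3.3)
})

test_that("orthogonalized power correlation handles collinearity and recovers shared amplitude", {
  X <- random_stack(60, seed = 28)
  Y <- X; Y$coeffs <- 2.5 * Y$coeffs          # collinear: no residual
  expect_true(all(is.na(orthogonalized_power_correlation(X, Y))))

  # independent carriers with a common amplitude modulation
  set.seed(29)
  nev <- 150
  g <- rexp(nev) + 0.2
  A <- fake_tfr(nev, 1:2, 1:5 / 10, function(e, f, t)
    g[e] * exp(1i * runif(length(t), 0, 2 * pi)))
  B <- fake_tfr(nev, 1:2, 1:5 / 10, function(e, f, t)
    g[e] * exp(1i * runif(length(t), 0, 2 * pi)))
  expect_gt(mean(orthogonalized_power_correlation(A, B), na.rm = TRUE), 0.5)

  A0 <- random_stack(150, seed = 30); B0 <- random_stack(150, seed = 31)
  expect_lt(mean(abs(orthogonalized_power_correlation(A0, B0)), na.rm = TRUE),
            2 / sqrt(150))
})

test_that("orthogonalization is robust to a common reference signal", {
  set.seed(32)
  nev <- 120; nt <- 6
  mkstack <- function(base) fake_tfr(nev, 1, seq_len(nt), base)
  ax <- rexp(nev) + 0.3; ay <- rexp(nev) + 0.3
  common <- complex(real = rnorm(nev), imaginary = rnorm(nev)) * 3
  X0 <- mkstack(function(e, f, t) ax[e] * exp(1i * runif(nt, 0, 2 * pi)))
  Y0 <- mkstack(function(e, f, t) ay[e] * exp(1i * runif(nt, 0, 2 * pi)))
  Xc <- X0; Yc <- Y0
  for (t in seq_len(nt)) {
    Xc$coeffs[, 1, t] <- Xc$coeffs[, 1, t] + common
    Yc$coeffs[, 1, t] <- Yc$coeffs[, 1, t] + common
  }
  raw0 <- mean(ripplelock:::corr_over_events(tfr_power(X0), tfr_power(Y0)))
  rawc <- mean(ripplelock:::corr_over_events(tfr_power(Xc), tfr_power(Yc)))
  orth0 <- mean(orthogonalized_power_correlation(X0, Y0), na.rm = TRUE)
  orthc <- mean(orthogonalized_power_correlation(Xc, Yc), na.rm = TRUE)
  expect_gt(rawc - raw0, 0.25)             # raw power correlation inflates
  expect_lt(abs(orthc - orth0), 0.15)      # orthogonalized stays put
})

simulate_var1 <- function(L, ntr, seed) {
  set.seed(seed)
  ex <- matrix(0, L, ntr); ey <- matrix(0, L, ntr)
  for (i in seq_len(ntr)) {
    burn <- 100
    x <- y <- numeric(L + burn)
    for (t in 2:(L + burn)) {
      x[t] <- 0.5 * x[t - 1] + rnorm(1)
      y[t] <- 0.4 * x[t - 1] + 0.4 * y[t - 1] + rnorm(1)
    }
    ex[, i] <- x[burn + seq_len(L)]
    ey[, i] <- y[burn + seq_len(L)]
  }
  list(x = ex, y = ey)
}

test_that("non-parametric PDC matches the analytic PDC of a known VAR", {
  fs <- 250; L <- 128
  tm <- (seq_len(L) - 1) / fs - 0.256
  A1 <- list(matrix(c(0.5, 0.4, 0, 0.4), 2, 2))
  batches <- lapply(1:6, function(b) {
    d <- simulate_var1(L, 80, seed = 300 + b)
    r <- pdc(d$x, d$y, fs, tm, t_range = c(0, 0))
    cbind(r$pdc_x_to_y[, 1], r$pdc_y_to_x[, 1])
  })
  est <- Reduce(`+`, batches) / 6
  # Monte-Carlo SD of a single replication (between-batch spread)
  mc_sd <- sqrt(Reduce(`+`, lapply(batches, function(b) (b - est)^2)) / 5)
  an <- var_pdc(A1, (0:(L / 2)) * fs / L, fs)
  ref <- cbind(an$x_to_y, an$y_to_x)
  sel <- 3:(L / 2 - 1)                      # away from DC / Nyquist taper bias
  # the driven direction must match closely; the null direction carries the
  # finite-trial magnitude bias E|z| = sqrt(pi/4n) of the 80-trial CSD, so
  # its floor is twice that theoretical bias
  dev <- abs(est - ref)
  expect_true(all(dev[sel, 1] <= pmax(3 * mc_sd[sel, 1], 0.06)))
  expect_true(all(dev[sel, 2] <= pmax(3 * mc_sd[sel, 2],
                                      2 * sqrt(pi / (4 * 80)))))
  # the driven direction clearly dominates
  expect_true(all(est[sel, 1] > est[sel, 2]))
})

test_that("PDC of independent channels is near-symmetric and label swap mirrors the maps", {
  fs <- 250; L <- 128
  tm <- (seq_len(L) - 1) / fs - 0.256
  set.seed(33)
  ex <- matrix(rnorm(L * 200), L); ey <- matrix(rnorm(L * 200), L)
  r <- pdc(ex, ey, fs, tm, t_range = c(0, 0))
  expect_lt(mean(r$pdc_x_to_y), 0.1)
  expect_lt(mean(r$pdc_y_to_x), 0.1)
  rs <- pdc(ey, ex, fs, tm, t_range = c(0, 0))
  expect_lt(max(abs(rs$pdc_x_to_y - r$pdc_y_to_x)), 1e-3)
  expect_lt(max(abs(rs$pdc_y_to_x - r$pdc_x_to_y)), 1e-3)
})

test_that("non-parametric PDC agrees with a least-squares parametric route", {
  fs <- 250; L <- 256
  tm <- (seq_len(L) - 1) / fs
  d <- simulate_var1(L, 150, seed = 40)
  r <- pdc(d$x, d$y, fs, tm, t_range = c(tm[L / 2], tm[L / 2]),
           window_len_s = 0.512)
  # parametric oracle: VAR(1) least squares on long concatenated data
  X <- rbind(as.vector(d$x[-L, ]), as.vector(d$y[-L, ]))
  Y <- rbind(as.vector(d$x[-1, ]), as.vector(d$y[-1, ]))
  Ahat <- Y %*% t(X) %*% solve(X %*% t(X))
  an <- var_pdc(list(Ahat), r$freq_hz, fs)
  sel <- 3:(length(r$freq_hz) - 2)
  expect_lt(mean(abs(r$pdc_x_to_y[sel, 1] - an$x_to_y[sel])), 0.08)
  expect_lt(mean(abs(r$pdc_y_to_x[sel, 1] - an$y_to_x[sel])), 0.08)
})

test_that("metrics stay within their bounds on arbitrary stacks", {
  A <- random_stack(30, seed = 50); B <- random_stack(30, seed = 51)
  expect_true(all(coherence(A, B) >= 0 & coherence(A, B) <= 1 + 1e-12))
  expect_true(all(plv(A, B) >= 0 & plv(A, B) <= 1 + 1e-12))
  oc <- orthogonalized_power_correlation(A, B)
  expect_true(all(abs(oc[!is.na(oc)]) <= 1 + 1e-12))
})
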