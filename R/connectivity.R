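# connectivity: trial-ensemble spectral coherence, phase locking,
# orthogonalized power correlation, and non-parametric partial directed
# coherence (PDC) between the neocortical and hippocampal channels.
#
# Coherence, PLV and the power correlations operate on aligned Morlet TFR
# stacks (event x frequency x time). PDC follows the non-parametric route:
# trial-averaged cross-spectral matrices on sliding 512 ms windows are
# factorized with the Wilson-Burg algorithm into a minimum-phase transfer
# function H(f) and noise covariance; the inverse transfer function takes
# the role of the spectral AR representation, and PDC is its column-wise
# (outflow) normalization.

check_aligned <- function(x, y) {
  stopifnot(inherits(x, "tfr_stack"), inherits(y, "tfr_stack"),
            identical(dim(x$coeffs), dim(y$coeffs)),
            identical(x$freq_hz, y$freq_hz))
}

#' Trial-ensemble magnitude coherence
#'
#' `|<X conj(Y)>| / sqrt(<|X|^2><|Y|^2>)` across events, per frequency and
#' time point.
#'
#' @param tfr_x,tfr_y aligned `tfr_stack` objects (same events).
#' @return matrix frequency x time in `[0, 1]`.
#' @export
coherence <- function(tfr_x, tfr_y) {
  check_aligned(tfr_x, tfr_y)
  n <- dim(tfr_x$coeffs)[1]
  if (n < 2) stop("coherence needs at least 2 trials (degenerate at 1)")
  X <- tfr_x$coeffs; Y <- tfr_y$coeffs
  sxy <- colMeans(X * Conj(Y))
  sxx <- colMeans(Mod(X)^2)
  syy <- colMeans(Mod(Y)^2)
  coh <- Mod(sxy) / sqrt(sxx * syy)
  dimnames(coh) <- NULL
  coh
}

#' Phase-locking value
#'
#' Magnitude of the trial-averaged unit phasor of the phase difference.
#'
#' @inheritParams coherence
#' @return matrix frequency x time in `[0, 1]`.
#' @export
plv <- function(tfr_x, tfr_y) {
  check_aligned(tfr_x, tfr_y)
  n <- dim(tfr_x$coeffs)[1]
  if (n < 2) stop("PLV needs at least 2 trials")
  Z <- tfr_x$coeffs * Conj(tfr_y$coeffs)
  Z <- Z / Mod(Z)
  Mod(colMeans(Z))
}

# Pearson correlation across the event dimension for every (f, t) cell.
corr_over_events <- function(A, B) {
  n <- dim(A)[1]
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colMeans(A^2) - ma^2
  vb <- colMeans(B^2) - mb^2
  cov <- colMeans(A * B) - ma * mb
  den <- sqrt(va * vb)
  out <- cov / den
  out[den < 1e-24] <- NA_real_
  out
}

#' Orthogonalized power correlation
#'
#' Removes the instantaneously in-phase component before correlating power
#' across trials: Y orthogonalized on X is `imag(Y conj(X) / |X|)`. The
#' correlation of power(X) with power(Y_|_X) and of power(X_|_Y) with
#' power(Y) are averaged. Cells with (near) collinear signals are invalid.
#'
#' @inheritParams coherence
#' @return matrix frequency x time of correlations in `[-1, 1]` (NA where
#'   invalid).
#' @export
orthogonalized_power_correlation <- function(tfr_x, tfr_y) {
  check_aligned(tfr_x, tfr_y)
  n <- dim(tfr_x$coeffs)[1]
  if (n < 3) stop("power correlation needs at least 3 trials")
  X <- tfr_x$coeffs; Y <- tfr_y$coeffs
  y_perp <- Im(Y * Conj(X) / Mod(X))
  x_perp <- Im(X * Conj(Y) / Mod(Y))
  r1 <- corr_over_events(Mod(X)^2, y_perp^2)
  r2 <- corr_over_events(x_perp^2, Mod(Y)^2)
  (r1 + r2) / 2
}

#' Frequency-band average of a time-frequency map
#'
#' @param metric matrix frequency x time.
#' @param freq_hz frequency axis.
#' @param band two-element band (inclusive).
#' @return time series (frequency mean within the band).
#' @export
band_mean <- function(metric, freq_hz, band = c(12, 16)) {
  sel <- freq_hz >= band[1] & freq_hz <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  colMeans(metric[sel, , drop = FALSE], na.rm = TRUE)
}

#' Mean of a time-frequency map over a rectangular window
#'
#' @param metric matrix frequency x time.
#' @param freq_hz,time_s axes of `metric`.
#' @param t_window,f_window inclusive window bounds in seconds / Hz.
#' @return scalar mean over the window (NA cells ignored).
#' @export
window_mean <- function(metric, freq_hz, time_s,
                        t_window = c(-0.22, 0.46), f_window = c(11.5, 18)) {
  fs_sel <- freq_hz >= f_window[1] & freq_hz <= f_window[2]
  ts_sel <- time_s >= t_window[1] & time_s <= t_window[2]
  if (!any(fs_sel) || !any(ts_sel)) stop("empty window selection")
  mean(metric[fs_sel, ts_sel], na.rm = TRUE)
}

# ---- Wilson-Burg spectral matrix factorization -----------------------------

# elementwise 2x2 complex matrix helpers over an array c(2, 2, N)
mul2 <- function(A, B) {
  C <- array(0i, dim(A))
  C[1, 1, ] <- A[1, 1, ] * B[1, 1, ] + A[1, 2, ] * B[2, 1, ]
  C[1, 2, ] <- A[1, 1, ] * B[1, 2, ] + A[1, 2, ] * B[2, 2, ]
  C[2, 1, ] <- A[2, 1, ] * B[1, 1, ] + A[2, 2, ] * B[2, 1, ]
  C[2, 2, ] <- A[2, 1, ] * B[1, 2, ] + A[2, 2, ] * B[2, 2, ]
  C
}

inv2 <- function(A) {
  det <- A[1, 1, ] * A[2, 2, ] - A[1, 2, ] * A[2, 1, ]
  B <- array(0i, dim(A))
  B[1, 1, ] <- A[2, 2, ] / det
  B[1, 2, ] <- -A[1, 2, ] / det
  B[2, 1, ] <- -A[2, 1, ] / det
  B[2, 2, ] <- A[1, 1, ] / det
  B
}

herm2 <- function(A) {
  B <- array(0i, dim(A))
  B[1, 1, ] <- Conj(A[1, 1, ]); B[2, 2, ] <- Conj(A[2, 2, ])
  B[1, 2, ] <- Conj(A[2, 1, ]); B[2, 1, ] <- Conj(A[1, 2, ])
  B
}

fft_entries <- function(A, inverse = FALSE) {
  N <- dim(A)[3]
  M <- matrix(0i, N, 4)
  M[, 1] <- A[1, 1, ]; M[, 2] <- A[2, 1, ]
  M[, 3] <- A[1, 2, ]; M[, 4] <- A[2, 2, ]
  Mf <- stats::mvfft(M, inverse = inverse)
  if (inverse) Mf <- Mf / N
  B <- array(0i, dim(A))
  B[1, 1, ] <- Mf[, 1]; B[2, 1, ] <- Mf[, 2]
  B[1, 2, ] <- Mf[, 3]; B[2, 2, ] <- Mf[, 4]
  B
}

# causal ("plus") operator: zero negative lags, halve and upper-triangularize
# lag zero
plus_operator <- function(G) {
  N <- dim(G)[3]
  gam <- fft_entries(G, inverse = TRUE)
  beta0 <- 0.5 * gam[, , 1]
  beta0[2, 1] <- 0i
  gam[, , 1] <- beta0
  gam[, , (N %/% 2 + 1):N] <- 0i
  fft_entries(gam)
}

# Wilson-Burg factorization of a full-circle 2x2 CSD: S = psi psi^H with
# psi minimum-phase. Returns psi and convergence flag.
wilson_factorize <- function(S, tol = 1e-9, max_iter = 200) {
  N <- dim(S)[3]
  gam0 <- Re(apply(S, c(1, 2), mean))
  # diagonal loading for numerical safety
  gam0 <- gam0 + diag(2) * 1e-12 * mean(diag(gam0))
  h <- t(chol(gam0))
  psi <- array(0i, c(2, 2, N))
  psi[1, 1, ] <- h[1, 1]; psi[2, 1, ] <- h[2, 1]; psi[2, 2, ] <- h[2, 2]
  I2 <- array(0i, c(2, 2, N)); I2[1, 1, ] <- 1; I2[2, 2, ] <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pinv <- inv2(psi)
    g <- mul2(mul2(pinv, S), herm2(pinv)) + I2
    gp <- plus_operator(g)
    psi_new <- mul2(psi, gp)
    delta <- max(Mod(psi_new - psi)) / max(max(Mod(psi)), 1e-300)
    if (!is.finite(delta)) break   # degenerate spectrum: report non-converged
    psi <- psi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(psi = psi, converged = converged)
}

# PDC from a factorized spectrum: Abar = A0 psi^{-1} is the spectral AR
# representation; column-normalize its magnitudes.
pdc_from_psi <- function(psi) {
  N <- dim(psi)[3]
  gam <- fft_entries(psi, inverse = TRUE)
  A0 <- Re(gam[, , 1])
  pinv <- inv2(psi)
  Abar <- array(0i, dim(psi))
  Abar[1, 1, ] <- A0[1, 1] * pinv[1, 1, ] + A0[1, 2] * pinv[2, 1, ]
  Abar[1, 2, ] <- A0[1, 1] * pinv[1, 2, ] + A0[1, 2] * pinv[2, 2, ]
  Abar[2, 1, ] <- A0[2, 1] * pinv[1, 1, ] + A0[2, 2] * pinv[2, 1, ]
  Abar[2, 2, ] <- A0[2, 1] * pinv[1, 2, ] + A0[2, 2] * pinv[2, 2, ]
  Am <- Mod(Abar)
  col1 <- sqrt(Am[1, 1, ]^2 + Am[2, 1, ]^2)
  col2 <- sqrt(Am[1, 2, ]^2 + Am[2, 2, ]^2)
  # pi_{i<-j}: influence of source j on target i
  list(x_to_y = Am[2, 1, ] / col1,    # source x (col 1) -> target y (row 2)
       y_to_x = Am[1, 2, ] / col2)    # source y (col 2) -> target x (row 1)
}

#' Analytic PDC of a bivariate VAR model
#'
#' Computes partial directed coherence directly from known VAR coefficient
#' matrices, for validation of the non-parametric estimate.
#'
#' @param A list of 2x2 coefficient matrices (lag 1, 2, ...).
#' @param freqs_hz frequencies at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return list with `x_to_y` and `y_to_x` over `freqs_hz`.
#' @export
var_pdc <- function(A, freqs_hz, fs) {
  out_xy <- numeric(length(freqs_hz))
  out_yx <- numeric(length(freqs_hz))
  for (k in seq_along(freqs_hz)) {
    Abar <- diag(2) + 0i
    for (r in seq_along(A))
      Abar <- Abar - A[[r]] * exp(-2i * pi * freqs_hz[k] * r / fs)
    Am <- Mod(Abar)
    out_xy[k] <- Am[2, 1] / sqrt(Am[1, 1]^2 + Am[2, 1]^2)
    out_yx[k] <- Am[1, 2] / sqrt(Am[1, 2]^2 + Am[2, 2]^2)
  }
  list(x_to_y = out_xy, y_to_x = out_yx)
}

#' Time-resolved non-parametric partial directed coherence
#'
#' Slides a `window_len_s` window in `step_s` steps across the epochs,
#' forms the trial-averaged cross-spectral matrix of the demeaned,
#' Hann-tapered window via the DFT, factorizes it (Wilson-Burg), and
#' computes column-normalized PDC for both directions.
#'
#' @param epochs_x,epochs_y matrices time x events (same grid), channel x
#'   and channel y.
#' @param fs sampling rate in Hz.
#' @param epoch_time_s epoch time axis (seconds relative to lock).
#' @param window_len_s sliding window length (0.512 s).
#' @param step_s window step (0.020 s).
#' @param t_range window-center range in seconds.
#' @param tol,max_iter Wilson-Burg convergence settings.
#' @return object of class `pdc_result`: `pdc_x_to_y`, `pdc_y_to_x`
#'   (frequency x time), `freq_hz`, `time_s`, `n_trials`, `converged`
#'   (per window; non-converged windows are NA).
#' @export
pdc <- function(epochs_x, epochs_y, fs, epoch_time_s,
                window_len_s = 0.512, step_s = 0.020, t_range = c(-1, 1),
                tol = 1e-9, max_iter = 200) {
  epochs_x <- as.matrix(epochs_x); epochs_y <- as.matrix(epochs_y)
  stopifnot(identical(dim(epochs_x), dim(epochs_y)))
  nev <- ncol(epochs_x)
  if (nev < 30)
    warning(sprintf("PDC estimated from only %d trials; below the stability floor of 30", nev))
  L <- round(window_len_s * fs)
  hl <- L %/% 2
  centers <- seq(t_range[1], t_range[2], by = step_s)
  keep <- centers - hl / fs >= epoch_time_s[1] - 1e-9 &
          centers + (L - hl - 1) / fs <= epoch_time_s[length(epoch_time_s)] + 1e-9
  centers <- centers[keep]
  taper <- hann_env(L)
  nf <- L %/% 2 + 1
  freq_hz <- (seq_len(nf) - 1) * fs / L
  p_xy <- matrix(NA_real_, nf, length(centers))
  p_yx <- matrix(NA_real_, nf, length(centers))
  conv <- logical(length(centers))
  for (w in seq_along(centers)) {
    c_idx <- which.min(abs(epoch_time_s - centers[w]))
    idx <- (c_idx - hl):(c_idx - hl + L - 1)
    Xs <- epochs_x[idx, , drop = FALSE]
    Ys <- epochs_y[idx, , drop = FALSE]
    Xs <- sweep(Xs, 2, colMeans(Xs)) * taper
    Ys <- sweep(Ys, 2, colMeans(Ys)) * taper
    Xf <- stats::mvfft(Xs); Yf <- stats::mvfft(Ys)
    S <- array(0i, c(2, 2, L))
    S[1, 1, ] <- rowMeans(Xf * Conj(Xf))
    S[2, 2, ] <- rowMeans(Yf * Conj(Yf))
    S[1, 2, ] <- rowMeans(Xf * Conj(Yf))
    S[2, 1, ] <- Conj(S[1, 2, ])
    fac <- tryCatch(wilson_factorize(S, tol, max_iter),
                    error = function(e) list(converged = FALSE))
    conv[w] <- fac$converged
    if (!fac$converged) next
    pd <- pdc_from_psi(fac$psi)
    p_xy[, w] <- pd$x_to_y[seq_len(nf)]
    p_yx[, w] <- pd$y_to_x[seq_len(nf)]
  }
  if (!all(conv))
    warning(sprintf("%d of %d PDC windows did not converge", sum(!conv),
                    length(conv)))
  structure(list(pdc_x_to_y = p_xy, pdc_y_to_x = p_yx, freq_hz = freq_hz,
                 time_s = centers, n_trials = nev, converged = conv,
                 window_len_s = window_len_s, step_s = step_s),
            class = "pdc_result")
}

#' @export
print.pdc_result <- function(x, ...) {
  cat(sprintf("<pdc_result> %d freqs x %d windows (%.3f s / %.0f ms), %d trials\n",
              length(x$freq_hz), length(x$time_s), x$window_len_s,
              1000 * x$step_s, x$n_trials))
  invisible(x)
}

#' Directional z-difference time course of PDC versus controls
#'
#' Band-averages PDC for both directions, z-scores each direction per time
#' bin against the distribution over the control sets, and returns
#' `z(x->y) - z(y->x)`. When a coherence-significance mask is supplied,
#' values outside significant coherence bins are set to NA (the full trace
#' is kept as an attribute).
#'
#' @param pdc_emp empirical `pdc_result`.
#' @param pdc_controls list of `pdc_result`, one per control set.
#' @param band frequency band in Hz (12-16).
#' @param coh_sig optional logical vector per time bin (significant
#'   coherence).
#' @return list: `z_diff`, `z_x_to_y`, `z_y_to_x`, `time_s`.
#' @export
pdc_direction_timecourse <- function(pdc_emp, pdc_controls, band = c(12, 16),
                                     coh_sig = NULL) {
  bm <- function(p) rbind(band_mean(p$pdc_x_to_y, p$freq_hz, band),
                          band_mean(p$pdc_y_to_x, p$freq_hz, band))
  emp <- bm(pdc_emp)
  ctrl <- vapply(pdc_controls, bm,
                 matrix(0, 2, length(pdc_emp$time_s)))
  mu <- apply(ctrl, c(1, 2), mean, na.rm = TRUE)
  sdv <- apply(ctrl, c(1, 2), stats::sd, na.rm = TRUE)
  bad <- sdv == 0 | is.na(sdv)
  sdv[bad] <- NA
  z <- (emp - mu) / sdv
  z_diff <- z[1, ] - z[2, ]
  full <- z_diff
  if (!is.null(coh_sig)) z_diff[!coh_sig] <- NA_real_
  structure(list(z_diff = z_diff, z_x_to_y = z[1, ], z_y_to_x = z[2, ],
                 time_s = pdc_emp$time_s),
            unmasked = full)
}
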