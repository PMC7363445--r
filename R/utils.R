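# Shared numeric helpers: zero-phase filtering, moving statistics,
# interval arithmetic on sample masks.

nextpow2 <- function(n) 2^ceiling(log2(max(n, 2)))

raised_cosine_ramp <- function(f, a, b) {
  a <- max(a, 0)
  r <- (f - a) / max(b - a, .Machine$double.eps)
  r[r < 0] <- 0
  r[r > 1] <- 1
  0.5 * (1 - cos(pi * r))
}

#' Zero-phase band-pass filter
#'
#' Filters a signal with a zero-phase frequency-domain filter whose
#' magnitude response is flat in the pass band and rolls off over a
#' raised-cosine transition at each edge. The signal is reflection-padded
#' before transforming so that edge effects stay local.
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate in Hz.
#' @param low lower pass-band edge in Hz, or `NULL` for a low-pass filter.
#' @param high upper pass-band edge in Hz, or `NULL` for a high-pass filter.
#' @param trans_frac transition width as a fraction of each edge frequency.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = NULL, high = NULL, trans_frac = 0.1) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  if (!is.null(high) && high >= fs / 2) high <- NULL
  if (!is.null(low) && low <= 0) low <- NULL
  if (is.null(low) && is.null(high)) return(x)
  pad_s <- if (!is.null(low)) 2 / low else 0.2
  npad <- min(n, ceiling(fs * pad_s))
  # pad to a power of two (mirror tiling): R's mixed-radix FFT degrades
  # badly on awkward lengths
  m <- nextpow2(n + 2 * npad)
  total_pad <- m - n
  pl <- total_pad %/% 2L
  mirror_idx <- function(i) {
    p <- (i - 1L) %% (2L * n)
    ifelse(p < n, p + 1L, 2L * n - p)
  }
  idx <- seq.int(1L - pl, m - pl)
  xp <- x[mirror_idx(idx)]
  # odd reflection about the edge values preserves the slope across the
  # boundary, avoiding derivative kinks in the padded signal
  left <- idx < 1L
  right <- idx > n
  if (any(left)) xp[left] <- 2 * x[1] - xp[left]
  if (any(right)) xp[right] <- 2 * x[n] - xp[right]
  fgrid <- (seq_len(m) - 1) / m * fs
  fgrid <- pmin(fgrid, fs - fgrid)
  g <- rep(1, m)
  if (!is.null(low)) {
    w <- max(low * trans_frac, 0.02)
    g <- g * raised_cosine_ramp(fgrid, low - w, low)
  }
  if (!is.null(high)) {
    w <- max(high * trans_frac, 0.5)
    g <- g * (1 - raised_cosine_ramp(fgrid, high, min(high + w, fs / 2)))
  }
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[pl + seq_len(n)]
}

# Pre-filter for threshold-based artifact scoring: causal first-order
# (6 dB/octave) high-pass — matching the gentle low edge of clinical
# acquisition chains, which preserves the onset amplitude of step-like
# excursions — followed by a zero-phase 150 Hz low-pass.
acquisition_filter <- function(x, fs, low = 0.3, high = 150) {
  a <- exp(-2 * pi * low / fs)
  n <- length(x)
  # warm the recursive filter up on an odd reflection of the signal start
  # (preserves level and slope), so ramps produce no start-up transient
  npad <- min(n - 1L, ceiling(12 * fs / (2 * pi * low)))
  xp <- c(2 * x[1] - x[seq(npad + 1L, 2L)], x)
  y <- stats::filter(c(xp[1], diff(xp)), a, method = "recursive")
  y <- as.numeric(y)[npad + seq_len(n)]
  as.numeric(bandpass_filter(y, fs, low = NULL, high = high))
}

# Centered moving average with shrinking windows at the edges.
moving_mean <- function(x, w) {
  n <- length(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Low-pass + subsample; used to bring epochs to an analysis rate.
decimate_signal <- function(x, fs, factor) {
  if (factor <= 1) return(x)
  y <- bandpass_filter(x, fs, low = NULL, high = 0.4 * fs / factor)
  y[seq(1L, length(y), by = factor)]
}

# ---- sample-interval helpers (1-based, inclusive) --------------------------

runs_true <- function(b) {
  if (!any(b)) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

intervals_to_mask <- function(iv, n) {
  m <- logical(n)
  if (is.null(iv) || nrow(iv) == 0) return(m)
  for (i in seq_len(nrow(iv))) {
    a <- max(1L, iv[i, 1]); b <- min(n, iv[i, 2])
    if (a <= b) m[a:b] <- TRUE
  }
  m
}

pad_intervals <- function(iv, pad, n) {
  if (nrow(iv) == 0) return(iv)
  cbind(start = pmax(1L, iv[, 1] - pad), end = pmin(n, iv[, 2] + pad))
}

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- list(iv[1, ])
  for (i in 2:nrow(iv)) {
    last <- out[[length(out)]]
    if (iv[i, 1] <= last[2] + 1L) {
      out[[length(out)]] <- c(last[1], max(last[2], iv[i, 2]))
    } else {
      out[[length(out)]] <- last
      out[[length(out) + 1L]] <- iv[i, ]
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Deterministic child seeds below 2^31 derived from a base seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
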