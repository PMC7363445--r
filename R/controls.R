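# control_events: duration-matched, ripple-free, artifact-free NREM
# surrogate events drawn around each empirical ripple, Gaussian-weighted
# within +/- 10 min, repeated for 100 sets.

#' Control-event sampling parameters
#'
#' @param n_sets number of surrogate sets (100).
#' @param halfwindow_s half-width of the sampling window around each ripple
#'   (600 s = 10 min).
#' @param gaussian_sd_s SD of the Gaussian weighting of candidate centers
#'   relative to the ripple peak (truncated at the window edge).
#' @param pad_s ripple-free / artifact-free padding required before and
#'   after each surrogate (1.5 s).
#' @param widen_step_s window widening increment on exhaustion (300 s).
#' @param seed integer seed.
#' @return list of class `control_params`.
#' @export
control_params <- function(n_sets = 100, halfwindow_s = 600,
                           gaussian_sd_s = 200, pad_s = 1.5,
                           widen_step_s = 300, seed = 1L) {
  structure(list(n_sets = n_sets, halfwindow_s = halfwindow_s,
                 gaussian_sd_s = gaussian_sd_s, pad_s = pad_s,
                 widen_step_s = widen_step_s, seed = as.integer(seed)),
            class = "control_params")
}

#' Draw matched ripple-free control events
#'
#' For each empirical ripple and each of `n_sets` iterations, draws one
#' surrogate interval of identical duration whose span padded by `pad_s` is
#' entirely artifact-free NREM without any detected ripple. Candidate
#' centers are drawn from a Gaussian centered on the ripple peak, truncated
#' at `halfwindow_s`. Surrogate cores never overlap each other across sets;
#' when a ripple's window is exhausted it is widened in `widen_step_s`
#' increments with a warning.
#'
#' @param ripples ripple event table (uses `id`, `peak_s`, `duration_s`,
#'   `onset_s`, `offset_s`).
#' @param clean_nrem per-sample logical: artifact-free NREM.
#' @param fs sampling rate in Hz.
#' @param params a [control_params()] list.
#' @return object of class `control_sets`: data.frame `sets`
#'   (`set`, `ripple_id`, `center_s`, `duration_s`) plus `params`.
#' @export
draw_control_sets <- function(ripples, clean_nrem, fs,
                              params = control_params()) {
  if (nrow(ripples) == 0) stop("ripple list is empty")
  n <- length(clean_nrem)
  set.seed(params$seed)
  # eligibility at sample level: clean NREM with no detected ripple
  elig <- clean_nrem
  for (i in seq_len(nrow(ripples))) {
    a <- max(1L, round(ripples$onset_s[i] * fs) + 1L)
    b <- min(n, round(ripples$offset_s[i] * fs))
    if (a <= b) elig[a:b] <- FALSE
  }
  bad_cs <- cumsum(!elig)
  span_clean <- function(lo, hi) {
    lo <- as.integer(lo); hi <- as.integer(hi)
    if (lo < 1L || hi > n) return(FALSE)
    (bad_cs[hi] - if (lo > 1L) bad_cs[lo - 1L] else 0L) == 0L
  }
  occupied <- logical(n)
  occ_free <- function(lo, hi) !any(occupied[lo:hi])
  out <- vector("list", params$n_sets * nrow(ripples))
  k <- 0L
  widened <- 0L
  for (s in seq_len(params$n_sets)) {
    for (i in seq_len(nrow(ripples))) {
      d <- ripples$duration_s[i]
      hd <- round(d / 2 * fs)
      hp <- hd + round(params$pad_s * fs)
      pk <- ripples$peak_s[i]
      win <- params$halfwindow_s
      center <- NA_real_
      repeat {
        for (try in seq_len(600L)) {
          off <- stats::rnorm(1, 0, params$gaussian_sd_s)
          if (abs(off) > win) next
          c_smp <- round((pk + off) * fs) + 1L
          if (c_smp - hp < 1L || c_smp + hp > n) next
          if (!span_clean(c_smp - hp, c_smp + hp)) next
          if (!occ_free(c_smp - hd, c_smp + hd)) next
          center <- (c_smp - 1L) / fs
          break
        }
        if (!is.na(center)) break
        if (win >= n / fs) {
          # last resort: enumerate candidate centers on a coarse grid
          grid <- seq(hp + 1L, n - hp, by = max(1L, round(fs * 0.05)))
          ok <- vapply(grid, function(cc)
            span_clean(cc - hp, cc + hp) && occ_free(cc - hd, cc + hd), TRUE)
          if (!any(ok)) stop(sprintf(
            "control sampling exhausted for ripple id %s", ripples$id[i]))
          w <- stats::dnorm((grid[ok] - 1) / fs - pk, 0, params$gaussian_sd_s)
          cc <- if (length(grid[ok]) == 1L) grid[ok]
                else sample(grid[ok], 1, prob = pmax(w, 1e-300))
          center <- (cc - 1L) / fs
          break
        }
        win <- win + params$widen_step_s
        widened <- widened + 1L
      }
      c_smp <- round(center * fs) + 1L
      occupied[(c_smp - hd):(c_smp + hd)] <- TRUE
      k <- k + 1L
      out[[k]] <- data.frame(set = s, ripple_id = ripples$id[i],
                             center_s = center, duration_s = d)
    }
  }
  if (widened > 0)
    warning(sprintf("control window widened %d times beyond +/-%g s",
                    widened, params$halfwindow_s))
  structure(list(sets = do.call(rbind, out[seq_len(k)]), params = params),
            class = "control_sets")
}

#' @export
print.control_sets <- function(x, ...) {
  cat(sprintf("<control_sets> %d sets x %d surrogates\n",
              max(x$sets$set), nrow(x$sets) / max(x$sets$set)))
  invisible(x)
}

#' Average per-set control quantities into one paired control per ripple
#'
#' @param per_set list of equally shaped numeric arrays (one per control
#'   set, e.g. per-ripple TFR power).
#' @return elementwise mean across sets.
#' @export
average_control_epochs <- function(per_set) {
  stopifnot(length(per_set) >= 1)
  d <- dim(per_set[[1]])
  for (a in per_set)
    if (!identical(dim(a), d)) stop("control set shapes differ")
  Reduce(`+`, per_set) / length(per_set)
}

#' Audit control-set constraints
#'
#' Re-checks every surrogate against the constraints it was drawn under:
#' exact duration match, padded span inside clean ripple-free NREM, center
#' within the sampling window of its ripple, and pairwise core non-overlap
#' across all sets.
#'
#' @param controls a `control_sets` object.
#' @param ripples the ripple table used to draw it.
#' @param clean_nrem per-sample logical clean-NREM mask.
#' @param fs sampling rate in Hz.
#' @return named integer vector of violation counts (all zero when valid).
#' @export
audit_control_sets <- function(controls, ripples, clean_nrem, fs) {
  cs <- controls$sets
  p <- controls$params
  n <- length(clean_nrem)
  elig <- clean_nrem
  for (i in seq_len(nrow(ripples))) {
    a <- max(1L, round(ripples$onset_s[i] * fs) + 1L)
    b <- min(n, round(ripples$offset_s[i] * fs))
    if (a <= b) elig[a:b] <- FALSE
  }
  dur_ok <- abs(cs$duration_s -
                ripples$duration_s[match(cs$ripple_id, ripples$id)]) < 1e-9
  span_bad <- vapply(seq_len(nrow(cs)), function(j) {
    c_smp <- round(cs$center_s[j] * fs) + 1L
    hp <- round(cs$duration_s[j] / 2 * fs) + round(p$pad_s * fs)
    lo <- c_smp - hp; hi <- c_smp + hp
    lo < 1L || hi > n || !all(elig[lo:hi])
  }, TRUE)
  win_bad <- abs(cs$center_s -
                 ripples$peak_s[match(cs$ripple_id, ripples$id)]) >
    p$halfwindow_s + 1e-9
  # pairwise core overlap across all surrogates
  lo <- cs$center_s - cs$duration_s / 2
  hi <- cs$center_s + cs$duration_s / 2
  ord <- order(lo)
  overlap <- sum(lo[ord][-1] < hi[ord][-length(ord)] - 1e-9)
  c(duration_mismatch = sum(!dur_ok), span_violation = sum(span_bad),
    window_violation = sum(win_bad), core_overlap = overlap)
}
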