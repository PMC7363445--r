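# stats: z-statistics against the 100-control-set distribution,
# cluster-based permutation tests on paired TFR contrasts, peri-event onset
# histograms, ripple-duration tertile analyses, duration-power correlations
# and event-contingency rates.

#' z-statistic of an empirical value against control sets
#'
#' @param empirical scalar empirical value.
#' @param controls numeric vector of per-control-set values (typically 100).
#' @return list of class `z_stat`: `value`, `p_two_sided`, `empirical`,
#'   `control_mean`, `control_sd`, `n_controls`. Significant at |z| > 1.96.
#' @export
z_vs_controls <- function(empirical, controls) {
  controls <- controls[is.finite(controls)]
  sdv <- stats::sd(controls)
  if (!isTRUE(sdv > 0)) stop("control distribution has zero spread")
  z <- (empirical - mean(controls)) / sdv
  structure(list(value = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
                 empirical = empirical, control_mean = mean(controls),
                 control_sd = sdv, n_controls = length(controls)),
            class = "z_stat")
}

#' @export
print.z_stat <- function(x, ...) {
  cat(sprintf("z = %.3f (empirical %.4g vs controls %.4g +/- %.4g, n=%d), p = %.4g\n",
              x$value, x$empirical, x$control_mean, x$control_sd,
              x$n_controls, x$p_two_sided))
  invisible(x)
}

# connected components of a logical matrix, 4-neighborhood; iterative
# minimum-label propagation (grids here are small)
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  if (!any(m)) return(lab)
  L <- matrix(Inf, nrow(m), ncol(m))
  L[m] <- seq_len(sum(m))
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    up    <- rbind(L[-1, , drop = FALSE], rep(Inf, nc))
    down  <- rbind(rep(Inf, nc), L[-nr, , drop = FALSE])
    left  <- cbind(L[, -1, drop = FALSE], rep(Inf, nr))
    right <- cbind(rep(Inf, nr), L[, -nc, drop = FALSE])
    Lnew <- pmin(L, up, down, left, right)
    Lnew[!m] <- Inf
    if (identical(Lnew, L)) break
    L <- Lnew
  }
  ids <- sort(unique(L[is.finite(L)]))
  lab[m] <- match(L[m], ids)
  lab
}

# max |cluster mass| of a t-map at a two-sided threshold
max_cluster_mass <- function(tmap, tcrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmap) > tcrit
    if (!any(mask)) next
    lab <- label_components(mask)
    masses <- abs(rowsum(tmap[mask], lab[mask]))
    best <- max(best, masses)
  }
  best
}

#' Cluster-based permutation test on paired time-frequency stacks
#'
#' Computes a paired t-map (event minus its averaged control), thresholds
#' it two-sided at the cluster alpha, clusters supra-threshold neighboring
#' cells (4-connectivity in the frequency x time grid), and compares each
#' cluster's summed t against the permutation distribution of the maximum
#' cluster mass under random within-pair sign flips.
#'
#' @param stack_event,stack_control numeric arrays pair x frequency x time
#'   (e.g. ripple-locked power and averaged-control power, paired by event).
#' @param cluster_alpha cell-level threshold for cluster formation (0.05).
#' @param n_perm number of sign-flip permutations (1000).
#' @param seed integer seed.
#' @return list of class `cluster_result`: `t_map`, `clusters` (data.frame
#'   `id`, `mass`, `n_cells`, `p_corrected`), `label_map`, `threshold_t`,
#'   `n_perm`.
#' @export
cluster_permutation <- function(stack_event, stack_control,
                                cluster_alpha = 0.05, n_perm = 1000,
                                seed = 1L) {
  stopifnot(identical(dim(stack_event), dim(stack_control)))
  n <- dim(stack_event)[1]
  if (n < 5) stop("cluster permutation needs at least 5 pairs")
  set.seed(as.integer(seed))
  d <- stack_event - stack_control
  nf <- dim(d)[2]; nt <- dim(d)[3]
  D <- matrix(d, n, nf * nt)
  ok_cell <- apply(is.finite(D), 2, all)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  ss <- colSums(D^2)
  t_of <- function(signs) {
    m <- as.vector(signs %*% D) / n
    v <- (ss - n * m^2) / (n - 1)
    tv <- m / sqrt(v / n)
    tv[!ok_cell | v <= 0] <- 0
    matrix(tv, nf, nt)
  }
  t_map <- t_of(matrix(1, 1, n))
  lab <- matrix(0L, nf, nt)
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * t_map) > tcrit
    if (!any(mask)) next
    l <- label_components(mask)
    offset <- length(clusters)
    for (k in seq_len(max(l))) {
      cells <- l == k
      clusters[[offset + k]] <- data.frame(
        id = offset + k, mass = sum(t_map[cells]), n_cells = sum(cells))
      lab[cells] <- offset + k
    }
  }
  perm_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- matrix(sample(c(-1, 1), n, replace = TRUE), 1, n)
    perm_max[p] <- max_cluster_mass(t_of(signs), tcrit)
  }
  cl <- if (length(clusters)) do.call(rbind, clusters)
        else data.frame(id = integer(), mass = numeric(), n_cells = integer())
  cl$p_corrected <- vapply(cl$mass, function(m)
    (1 + sum(perm_max >= abs(m))) / (n_perm + 1), numeric(1))
  structure(list(t_map = t_map, clusters = cl, label_map = lab,
                 threshold_t = tcrit, n_perm = n_perm,
                 perm_max = perm_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (|t| > %.2f), %d permutations\n",
              nrow(x$clusters), x$threshold_t, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Peri-event histogram of spindle onsets around ripples
#'
#' Counts spindle onsets in 50 ms bins relative to ripple peaks, normalized
#' by the total number of detected spindle onsets (x 100). When control
#' centers are given, each bin is z-scored against the per-set control
#' histograms; bins with |z| > 1.96 are flagged significant.
#'
#' @param spindles spindle event table (uses `onset_s`).
#' @param ripples ripple event table (uses `peak_s`).
#' @param control_centers optional matrix (sets x ripples) of control
#'   center times, or a `control_sets` object.
#' @param bin_s bin width in seconds (0.05).
#' @param range_s histogram half-range in seconds (0.5).
#' @return list of class `onset_histogram`: `bin_mid_s`, `value` (percent
#'   of all spindle onsets), `counts`, `z`, `significant`, `peak_bin_s`.
#' @export
spindle_onset_histogram <- function(spindles, ripples, control_centers = NULL,
                                    bin_s = 0.05, range_s = 0.5) {
  if (nrow(spindles) == 0) stop("no spindle events")
  breaks <- seq(-range_s, range_s, by = bin_s)
  mids <- breaks[-1] - bin_s / 2
  count_hist <- function(locks) {
    rel <- unlist(lapply(locks, function(pk) {
      d <- spindles$onset_s - pk
      d[d >= -range_s & d < range_s]
    }))
    if (!length(rel)) return(numeric(length(mids)))
    tabulate(findInterval(rel, breaks, rightmost.closed = FALSE,
                          left.open = FALSE), nbins = length(mids))
  }
  counts <- count_hist(ripples$peak_s)
  value <- counts / nrow(spindles) * 100
  z <- sig <- NULL
  if (!is.null(control_centers)) {
    if (inherits(control_centers, "control_sets")) {
      cs <- control_centers$sets
      control_centers <- do.call(rbind, lapply(split(cs$center_s, cs$set),
                                               function(v) v))
    }
    ctrl <- t(apply(control_centers, 1, count_hist)) / nrow(spindles) * 100
    mu <- colMeans(ctrl)
    sdv <- apply(ctrl, 2, stats::sd)
    z <- (value - mu) / ifelse(sdv > 0, sdv, NA)
    sig <- !is.na(z) & z > 1.96
  }
  structure(list(bin_mid_s = mids, value = value, counts = counts,
                 z = z, significant = sig,
                 peak_bin_s = mids[which.max(value)]),
            class = "onset_histogram")
}

#' @export
print.onset_histogram <- function(x, ...) {
  cat(sprintf("<onset_histogram> peak bin at %+.3f s (%.1f%% of onsets)\n",
              x$peak_bin_s, max(x$value)))
  invisible(x)
}

#' Split ripples into duration tertiles per patient
#'
#' Tertile boundaries use linearly interpolated quantiles at 1/3 and 2/3 of
#' the per-patient duration distribution; the first tertile is `short`, the
#' third `long`, and the middle (including boundary ties) is discarded.
#'
#' @param ripples event table with `duration_s` and optionally `patient`.
#' @return list: `short`, `long` (event tables), `thresholds` (per patient:
#'   `q_low`, `q_high`).
#' @export
tertile_split <- function(ripples) {
  if (!"patient" %in% names(ripples)) ripples$patient <- "p1"
  short <- long <- NULL
  thr <- list()
  for (p in unique(ripples$patient)) {
    ev <- ripples[ripples$patient == p, ]
    if (nrow(ev) < 3)
      stop(sprintf("patient %s has fewer than 3 ripples", p))
    q <- stats::quantile(ev$duration_s, c(1 / 3, 2 / 3), names = FALSE,
                         type = 7)
    if (q[1] == q[2])
      warning(sprintf("degenerate duration distribution for patient %s", p))
    short <- rbind(short, ev[ev$duration_s < q[1], ])
    long <- rbind(long, ev[ev$duration_s > q[2], ])
    thr[[p]] <- data.frame(patient = p, q_low = q[1], q_high = q[2])
  }
  list(short = short, long = long, thresholds = do.call(rbind, thr))
}

#' One-sided test of long- versus short-ripple power
#'
#' Independent-samples t-test (pooled variance), one-sided for
#' `long > short`.
#'
#' @param power_long,power_short numeric vectors of per-event power.
#' @return `htest` object from [stats::t.test()].
#' @export
long_vs_short_power_test <- function(power_long, power_short) {
  if (length(power_long) < 2 || length(power_short) < 2)
    stop("both groups need at least 2 events")
  if (stats::sd(c(power_long, power_short)) == 0)
    stop("degenerate (constant) power values")
  stats::t.test(power_long, power_short, alternative = "greater",
                var.equal = TRUE)
}

#' Group test of ripple-duration / spindle-power correlation
#'
#' Per patient, Spearman correlation between ripple duration and event
#' power; correlations are Fisher z-transformed (clipped at |r| =
#' 1 - 1e-12) and tested against zero with a one-sample t-test across
#' patients. Patients with constant durations are excluded with a warning.
#'
#' @param events data.frame with `patient`, `duration_s`, `power`.
#' @return list: `per_patient` (patient, r, z), `mean_r`, `t`, `df`, `p`
#'   (one-sided, positive direction) and `p_two_sided`.
#' @export
duration_power_correlation <- function(events) {
  per <- list()
  for (p in unique(events$patient)) {
    ev <- events[events$patient == p, ]
    if (stats::sd(ev$duration_s) == 0 || nrow(ev) < 3) {
      warning(sprintf("patient %s excluded (constant durations or too few events)", p))
      next
    }
    r <- stats::cor(ev$duration_s, ev$power, method = "spearman")
    per[[p]] <- data.frame(patient = p, r = r,
                           z = atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))
  }
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) < 3)
    stop("need at least 3 patients with usable correlations")
  if (stats::sd(per$z) == 0) {
    # boundary: identical correlations in every patient (e.g. all r = 1
    # after clipping); the t statistic degenerates, significance is decided
    # by the common sign
    t_val <- sign(mean(per$z)) * Inf
    return(list(per_patient = per, mean_r = mean(per$r), t = t_val,
                df = nrow(per) - 1,
                p = if (mean(per$z) > 0) 0 else 1,
                p_two_sided = if (mean(per$z) == 0) 1 else 0))
  }
  tt <- stats::t.test(per$z, mu = 0)
  list(per_patient = per, mean_r = mean(per$r),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = stats::pt(unname(tt$statistic), unname(tt$parameter),
                     lower.tail = FALSE),
       p_two_sided = tt$p.value)
}

#' Spindle-ripple event contingency
#'
#' @param spindles,ripples event tables.
#' @param window_s co-occurrence window in seconds (1).
#' @return list: `pct_spindles_near_ripples` (spindle onsets within
#'   `window_s` of any ripple peak, percent) and `pct_ripples_with_spindle`
#'   (ripples whose interval overlaps any spindle interval, percent).
#' @export
event_contingency <- function(spindles, ripples, window_s = 1) {
  if (nrow(spindles) == 0 || nrow(ripples) == 0)
    return(list(pct_spindles_near_ripples = 0, pct_ripples_with_spindle = 0))
  near <- vapply(spindles$onset_s, function(o)
    any(abs(o - ripples$peak_s) <= window_s), TRUE)
  olap <- vapply(seq_len(nrow(ripples)), function(i)
    any(spindles$onset_s < ripples$offset_s[i] &
        spindles$offset_s > ripples$onset_s[i]), TRUE)
  list(pct_spindles_near_ripples = 100 * mean(near),
       pct_ripples_with_spindle = 100 * mean(olap))
}
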