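# pipeline: config-driven orchestration of the full ripple-locked analysis
# chain on one recording - detection, surrogate controls, TFR power
# contrast with cluster statistics, coherence / PLV / orthogonalized power
# correlation, directional PDC, onset histograms and duration analyses.

#' Analysis configuration
#'
#' Bundles all stage parameters with the canonical defaults: spindle and
#' ripple detectors, 100 control sets within +/- 10 min, 1-20 Hz wavelet
#' grid in 0.5 Hz / 20 ms steps, the joint spindle window (-0.22 to 0.46 s,
#' 11.5-18 Hz), the 12-16 Hz band, 512 ms / 20 ms PDC windows, and
#' cluster permutation at alpha 0.05.
#'
#' @param seed integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param spindle_params,ripple_params [detector_params()] overrides.
#' @param control overrides for [control_params()].
#' @param wavelet overrides for [build_wavelet_spec()].
#' @param windows list: `t_window`, `f_window` (joint spindle cluster
#'   window), `band` (12-16 Hz), `pdc_window_len_s`, `pdc_step_s`,
#'   `t_range` (analysis range around the ripple peak).
#' @param stats list: `cluster_alpha`, `n_perm`, `bin_s`, `range_s`.
#' @param fs_tfr,fs_pdc analysis sampling rates after decimation (Hz).
#' @param epoch_half_s epoch half-width around lock points (3 s).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L,
                            spindle_params = list(),
                            ripple_params = list(),
                            control = list(),
                            wavelet = list(),
                            windows = list(),
                            stats = list(),
                            fs_tfr = 100, fs_pdc = 250,
                            epoch_half_s = 3) {
  structure(list(
    seed = as.integer(seed),
    spindle_params = do.call(detector_params, c(list(kind = "spindle"),
                                                spindle_params)),
    ripple_params = do.call(detector_params, c(list(kind = "ripple"),
                                               ripple_params)),
    control = do.call(control_params,
                      utils::modifyList(list(seed = derive_seed(seed, 2)),
                                        control)),
    wavelet = do.call(build_wavelet_spec, wavelet),
    windows = utils::modifyList(list(
      t_window = c(-0.22, 0.46), f_window = c(11.5, 18), band = c(12, 16),
      pdc_window_len_s = 0.512, pdc_step_s = 0.020, t_range = c(-1, 1)),
      windows),
    stats = utils::modifyList(list(
      cluster_alpha = 0.05, n_perm = 1000, bin_s = 0.05, range_s = 0.5),
      stats),
    fs_tfr = fs_tfr, fs_pdc = fs_pdc, epoch_half_s = epoch_half_s),
    class = "analysis_config")
}

# mean of a per-event power array over the joint window -> per-event scalar
event_window_power <- function(power, freq_hz, time_s, t_window, f_window) {
  fsel <- freq_hz >= f_window[1] & freq_hz <= f_window[2]
  tsel <- time_s >= t_window[1] & time_s <= t_window[2]
  apply(power[, fsel, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
}

#' Run the full ripple-locked coupling analysis on one recording
#'
#' Stages: artifact rejection, NREM pooling, spindle/ripple detection,
#' densities and contingencies, 100 matched ripple-free control sets,
#' ripple-locked wavelet power versus averaged controls with cluster
#' permutation statistics, NC-HIPP coherence / PLV / orthogonalized power
#' correlation (window z and 12-16 Hz time course z against controls),
#' directional PDC z-difference, peri-ripple spindle-onset histograms, and
#' ripple-duration tertile / correlation analyses.
#'
#' @param config an [analysis_config()].
#' @param sim result of [generate_recording()] (recording + hypnogram,
#'   optionally ground truth). Alternatively pass `recording` and
#'   `hypnogram` explicitly.
#' @param recording,hypnogram used when `sim` is NULL.
#' @param out_dir optional directory for result tables (JSON/TSV).
#' @return a report list; see the vignette for the layout.
#' @export
run_full_analysis <- function(config = analysis_config(), sim = NULL,
                              recording = NULL, hypnogram = NULL,
                              out_dir = NULL) {
  if (!is.null(sim)) {
    recording <- sim$recording
    hypnogram <- sim$hypnogram
  }
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(hypnogram, "hypnogram"))
  fs <- recording$fs
  n <- n_samples(recording)
  report <- list(config = config)

  # --- artifact rejection and pools --------------------------------------
  art <- detect_artifacts(recording, hypnogram)
  nrem <- nrem_mask(hypnogram, fs, n)
  clean_all <- nrem & !art$combined
  report$artifact <- list(
    masked_fraction = vapply(art$per_channel, function(m) mean(m$mask), 0),
    clean_nrem_s = sum(clean_all) / fs)

  # --- event detection ----------------------------------------------------
  x_nc <- channel_by_role(recording, "NC")
  x_hp <- channel_by_role(recording, "HIPP")
  m_nc <- art$per_channel[[which(recording$roles == "NC")[1]]]$mask
  m_hp <- art$per_channel[[which(recording$roles == "HIPP")[1]]]$mask
  sp_nc <- detect_events(x_nc, fs, m_nc, nrem, config$spindle_params, "NC")
  sp_hp <- detect_events(x_hp, fs, m_hp, nrem, config$spindle_params, "HIPP")
  ripples <- detect_events(x_hp, fs, m_hp, nrem, config$ripple_params, "HIPP")
  clean_nc_s <- sum(nrem & !m_nc) / fs
  clean_hp_s <- sum(nrem & !m_hp) / fs
  report$events <- list(
    spindles_nc = sp_nc, spindles_hipp = sp_hp, ripples = ripples,
    density = c(spindle_nc = event_density(sp_nc, clean_nc_s),
                spindle_hipp = event_density(sp_hp, clean_hp_s),
                ripple = event_density(ripples, clean_hp_s)),
    contingency_nc = event_contingency(sp_nc, ripples),
    contingency_hipp = event_contingency(sp_hp, ripples))

  if (nrow(ripples) == 0) {
    report$status <- "no ripples detected; ripple-locked analyses skipped"
    return(report)
  }
  report$status <- "complete"

  # --- matched control events ----------------------------------------------
  # keep surrogates clear of the recording edges so +/-3 s epochs always fit
  clean_ctrl <- clean_all
  edge <- round(config$epoch_half_s * fs)
  clean_ctrl[c(seq_len(edge), n - seq_len(edge) + 1L)] <- FALSE
  controls <- draw_control_sets(ripples, clean_ctrl, fs, config$control)
  report$controls <- controls
  report$clean_ctrl <- clean_ctrl

  # --- decimated channels and epoch machinery ------------------------------
  dec_t <- round(fs / config$fs_tfr)
  dec_p <- round(fs / config$fs_pdc)
  nc_t <- decimate_signal(x_nc, fs, dec_t); hp_t <- decimate_signal(x_hp, fs, dec_t)
  nc_p <- decimate_signal(x_nc, fs, dec_p); hp_p <- decimate_signal(x_hp, fs, dec_p)
  fs_t <- fs / dec_t; fs_p <- fs / dec_p
  half <- config$epoch_half_s
  spec <- config$wavelet
  w <- config$windows

  tfr_pair <- function(centers) {
    ep_nc <- extract_epochs(nc_t, fs_t, centers, half)
    ep_hp <- extract_epochs(hp_t, fs_t, centers, half)
    list(nc = compute_tfr(ep_nc$epochs, fs_t, spec, ep_nc$time_s,
                          t_range = w$t_range),
         hp = compute_tfr(ep_hp$epochs, fs_t, spec, ep_hp$time_s,
                          t_range = w$t_range),
         kept = ep_nc$kept)
  }
  pdc_pair <- function(centers) {
    ep_nc <- extract_epochs(nc_p, fs_p, centers, half)
    ep_hp <- extract_epochs(hp_p, fs_p, centers, half)
    pdc(ep_nc$epochs, ep_hp$epochs, fs_p, ep_nc$time_s,
        window_len_s = w$pdc_window_len_s, step_s = w$pdc_step_s,
        t_range = w$t_range)
  }

  emp <- tfr_pair(ripples$peak_s)
  kept <- emp$kept
  rip_kept <- ripples[kept, ]
  report$n_epochs <- sum(kept)
  pow_nc <- tfr_power(emp$nc); pow_hp <- tfr_power(emp$hp)
  coh_emp <- coherence(emp$nc, emp$hp)
  plv_emp <- plv(emp$nc, emp$hp)
  opc_emp <- orthogonalized_power_correlation(emp$nc, emp$hp)
  pdc_emp <- suppressWarnings(pdc_pair(ripples$peak_s[kept]))

  # --- per-control-set pass -------------------------------------------------
  n_sets <- config$control$n_sets
  csets <- split(controls$sets, controls$sets$set)
  acc_nc <- acc_hp <- 0
  coh_win <- plv_win <- opc_win <- numeric(n_sets)
  coh_band <- matrix(NA_real_, n_sets, length(emp$nc$time_s))
  pdc_ctrl <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    centers <- csets[[s]]$center_s[match(rip_kept$id, csets[[s]]$ripple_id)]
    ct <- tfr_pair(centers)
    acc_nc <- acc_nc + tfr_power(ct$nc)
    acc_hp <- acc_hp + tfr_power(ct$hp)
    coh_c <- coherence(ct$nc, ct$hp)
    coh_win[s] <- window_mean(coh_c, spec$freqs_hz, ct$nc$time_s,
                              w$t_window, w$f_window)
    coh_band[s, ] <- band_mean(coh_c, spec$freqs_hz, w$band)
    plv_win[s] <- window_mean(plv(ct$nc, ct$hp), spec$freqs_hz, ct$nc$time_s,
                              w$t_window, w$f_window)
    opc_win[s] <- window_mean(orthogonalized_power_correlation(ct$nc, ct$hp),
                              spec$freqs_hz, ct$nc$time_s,
                              w$t_window, w$f_window)
    pdc_ctrl[[s]] <- suppressWarnings(pdc_pair(centers))
  }
  ctrl_pow_nc <- acc_nc / n_sets
  ctrl_pow_hp <- acc_hp / n_sets

  # --- power contrast with cluster permutation -----------------------------
  report$tfr <- list(
    time_s = emp$nc$time_s, freq_hz = spec$freqs_hz,
    clusters_nc = cluster_permutation(pow_nc, ctrl_pow_nc,
                                      config$stats$cluster_alpha,
                                      config$stats$n_perm,
                                      seed = derive_seed(config$seed, 3)),
    clusters_hipp = cluster_permutation(pow_hp, ctrl_pow_hp,
                                        config$stats$cluster_alpha,
                                        config$stats$n_perm,
                                        seed = derive_seed(config$seed, 4)))

  # --- coherence / PLV / orthogonalized power correlation ------------------
  coh_band_emp <- band_mean(coh_emp, spec$freqs_hz, w$band)
  band_mu <- colMeans(coh_band); band_sd <- apply(coh_band, 2, stats::sd)
  coh_band_z <- (coh_band_emp - band_mu) / ifelse(band_sd > 0, band_sd, NA)
  report$coherence <- list(
    window_z = z_vs_controls(
      window_mean(coh_emp, spec$freqs_hz, emp$nc$time_s, w$t_window,
                  w$f_window), coh_win),
    band_timecourse_z = coh_band_z, time_s = emp$nc$time_s)
  report$plv <- list(window_z = z_vs_controls(
    window_mean(plv_emp, spec$freqs_hz, emp$nc$time_s, w$t_window,
                w$f_window), plv_win))
  report$power_correlation <- list(window_z = z_vs_controls(
    window_mean(opc_emp, spec$freqs_hz, emp$nc$time_s, w$t_window,
                w$f_window), opc_win))

  # --- directional PDC -----------------------------------------------------
  coh_sig_at <- function(times)
    approx_sig(emp$nc$time_s, coh_band_z > 1.96, times)
  pdc_dir <- pdc_direction_timecourse(pdc_emp, pdc_ctrl, band = w$band,
                                      coh_sig = coh_sig_at(pdc_emp$time_s))
  report$pdc <- c(
    unclass(pdc_dir),
    list(z_diff_unmasked = attr(pdc_dir, "unmasked"),
         window_z_nc_to_hipp = z_vs_controls(
      window_mean(pdc_emp$pdc_x_to_y, pdc_emp$freq_hz, pdc_emp$time_s,
                  w$t_window, w$f_window),
      vapply(pdc_ctrl, function(p)
        window_mean(p$pdc_x_to_y, p$freq_hz, p$time_s, w$t_window,
                    w$f_window), 0)),
      window_z_hipp_to_nc = z_vs_controls(
        window_mean(pdc_emp$pdc_y_to_x, pdc_emp$freq_hz, pdc_emp$time_s,
                    w$t_window, w$f_window),
        vapply(pdc_ctrl, function(p)
          window_mean(p$pdc_y_to_x, p$freq_hz, p$time_s, w$t_window,
                      w$f_window), 0))))

  # --- peri-ripple spindle-onset histograms --------------------------------
  ctrl_centers <- do.call(rbind, lapply(csets, function(cs)
    cs$center_s[match(rip_kept$id, cs$ripple_id)]))
  report$histograms <- list(
    nc = spindle_onset_histogram(sp_nc, rip_kept, ctrl_centers,
                                 config$stats$bin_s, config$stats$range_s),
    hipp = spindle_onset_histogram(sp_hp, rip_kept, ctrl_centers,
                                   config$stats$bin_s, config$stats$range_s))

  # --- duration analyses ---------------------------------------------------
  pw_nc <- event_window_power(pow_nc, spec$freqs_hz, emp$nc$time_s,
                              w$t_window, w$f_window)
  pw_hp <- event_window_power(pow_hp, spec$freqs_hz, emp$nc$time_s,
                              w$t_window, w$f_window)
  ts <- tertile_split(rip_kept)
  in_short <- rip_kept$id %in% ts$short$id
  in_long <- rip_kept$id %in% ts$long$id
  report$duration <- list(
    thresholds = ts$thresholds,
    n_short = sum(in_short), n_long = sum(in_long),
    test_nc = long_vs_short_power_test(pw_nc[in_long], pw_nc[in_short]),
    test_hipp = long_vs_short_power_test(pw_hp[in_long], pw_hp[in_short]),
    power_nc = pw_nc, power_hipp = pw_hp,
    spearman_nc = stats::cor(rip_kept$duration_s, pw_nc, method = "spearman"),
    spearman_hipp = stats::cor(rip_kept$duration_s, pw_hp,
                               method = "spearman"))

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Per-ripple spindle-band power table
#'
#' Lightweight path for duration analyses: detects ripples, computes the
#' ripple-locked wavelet power of both channels, and returns the mean power
#' in the joint spindle window per event, without the surrogate-control and
#' connectivity stages.
#'
#' @param recording an `eeg_recording`.
#' @param hypnogram a `hypnogram`.
#' @param config an [analysis_config()].
#' @return data.frame: `id`, `duration_s`, `power_nc`, `power_hipp`.
#' @export
ripple_power_table <- function(recording, hypnogram,
                               config = analysis_config()) {
  fs <- recording$fs
  n <- n_samples(recording)
  art <- detect_artifacts(recording, hypnogram)
  nrem <- nrem_mask(hypnogram, fs, n)
  x_nc <- channel_by_role(recording, "NC")
  x_hp <- channel_by_role(recording, "HIPP")
  m_hp <- art$per_channel[[which(recording$roles == "HIPP")[1]]]$mask
  ripples <- detect_events(x_hp, fs, m_hp, nrem, config$ripple_params, "HIPP")
  if (nrow(ripples) == 0)
    return(data.frame(id = integer(), duration_s = numeric(),
                      power_nc = numeric(), power_hipp = numeric()))
  dec <- round(fs / config$fs_tfr)
  fs_t <- fs / dec
  nc_d <- decimate_signal(x_nc, fs, dec)
  hp_d <- decimate_signal(x_hp, fs, dec)
  spec <- config$wavelet
  w <- config$windows
  ep_nc <- extract_epochs(nc_d, fs_t, ripples$peak_s, config$epoch_half_s)
  ep_hp <- extract_epochs(hp_d, fs_t, ripples$peak_s, config$epoch_half_s)
  tf_nc <- compute_tfr(ep_nc$epochs, fs_t, spec, ep_nc$time_s, w$t_range)
  tf_hp <- compute_tfr(ep_hp$epochs, fs_t, spec, ep_hp$time_s, w$t_range)
  kept <- ripples[ep_nc$kept, ]
  data.frame(
    id = kept$id, duration_s = kept$duration_s,
    power_nc = event_window_power(tfr_power(tf_nc), spec$freqs_hz,
                                  tf_nc$time_s, w$t_window, w$f_window),
    power_hipp = event_window_power(tfr_power(tf_hp), spec$freqs_hz,
                                    tf_hp$time_s, w$t_window, w$f_window))
}

# nearest-neighbour lookup of a logical significance trace on a new axis
approx_sig <- function(time_s, sig, at) {
  sig[is.na(sig)] <- FALSE
  idx <- vapply(at, function(t) which.min(abs(time_s - t)), 0L)
  sig[idx]
}

#' Write the analysis report to disk
#'
#' Event tables and control sets as TSV, numeric summaries as JSON.
#'
#' @param report result of [run_full_analysis()].
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- report$events
  write_events(ev$spindles_nc, file.path(dir, "spindles_nc.tsv"))
  write_events(ev$spindles_hipp, file.path(dir, "spindles_hipp.tsv"))
  write_events(ev$ripples, file.path(dir, "ripples.tsv"))
  if (!is.null(report$controls))
    utils::write.table(report$controls$sets,
                       file.path(dir, "control_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    status = report$status,
    density = as.list(ev$density),
    contingency_nc = ev$contingency_nc,
    contingency_hipp = ev$contingency_hipp,
    clean_nrem_s = report$artifact$clean_nrem_s)
  if (!is.null(report$coherence)) {
    summary$coherence_window_z <- report$coherence$window_z$value
    summary$plv_window_z <- report$plv$window_z$value
    summary$power_correlation_window_z <- report$power_correlation$window_z$value
    summary$pdc_window_z_nc_to_hipp <- report$pdc$window_z_nc_to_hipp$value
    summary$pdc_window_z_hipp_to_nc <- report$pdc$window_z_hipp_to_nc$value
    summary$pdc_max_z_diff <- max(report$pdc$z_diff, na.rm = TRUE)
    summary$histogram_peak_nc_s <- report$histograms$nc$peak_bin_s
    summary$histogram_peak_hipp_s <- report$histograms$hipp$peak_bin_s
    summary$tertile_thresholds <- as.list(report$duration$thresholds[1, c("q_low", "q_high")])
    summary$clusters_nc <- report$tfr$clusters_nc$clusters
    summary$clusters_hipp <- report$tfr$clusters_hipp$clusters
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
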