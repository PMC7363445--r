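#!/usr/bin/env Rscript
# Artifact rejection and spindle/ripple detection on the simulated nights
# written by 01_simulate_nights.R, read back from EDF as a real analysis
# would. Scores detection against the injected ground truth and writes the
# event tables, densities and the artifact interval tables.

suppressMessages(library(ripplelock))

indir <- "results/simulated"
out <- "results/detection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
fs <- 1000

for (nm in c("detection_night", "coupling_night")) {
  message("== ", nm, " ==")
  rec <- read_recording(file.path(indir, nm, "recording.edf"), "edf",
                        require_roles = c("NC", "HIPP"))
  hyp <- read_hypnogram(file.path(indir, nm, "hypnogram.txt"))
  truth <- read_events(file.path(indir, nm, "truth_events.tsv"))

  art <- detect_artifacts(rec, hyp)
  nrem <- nrem_mask(hyp, fs, nrow(rec$signals))
  for (ch in names(art$per_channel))
    mask_intervals_table(art$per_channel[[ch]], fs,
                         file.path(out, sprintf("%s_artifacts_%s.tsv", nm, ch)))

  m_nc <- art$per_channel$NC$mask
  m_hp <- art$per_channel$HIPP$mask
  sp_nc <- detect_events(rec$signals[, "NC"], fs, m_nc, nrem,
                         detector_params("spindle"), "NC")
  sp_hp <- detect_events(rec$signals[, "HIPP"], fs, m_hp, nrem,
                         detector_params("spindle"), "HIPP")
  rp <- detect_events(rec$signals[, "HIPP"], fs, m_hp, nrem,
                      detector_params("ripple"), "HIPP")
  write_events(sp_nc, file.path(out, paste0(nm, "_spindles_nc.tsv")))
  write_events(sp_hp, file.path(out, paste0(nm, "_spindles_hipp.tsv")))
  write_events(rp, file.path(out, paste0(nm, "_ripples.tsv")))

  score <- function(det, kind, channel) {
    m <- match_events(det, truth[truth$kind == kind & truth$channel == channel, ])
    message(sprintf("  %s %s: n=%d, precision %.2f, recall %.2f, F1 %.2f",
                    channel, kind, m$n_detected, m$precision, m$recall, m$f1))
    m
  }
  scores <- list(spindle_nc = score(sp_nc, "spindle", "NC"),
                 spindle_hipp = score(sp_hp, "spindle", "HIPP"),
                 ripple = score(rp, "ripple", "HIPP"))
  dens <- c(spindle_nc = event_density(sp_nc, sum(nrem & !m_nc) / fs),
            spindle_hipp = event_density(sp_hp, sum(nrem & !m_hp) / fs),
            ripple = event_density(rp, sum(nrem & !m_hp) / fs))
  message(sprintf("  densities/min: NC spindle %.1f, HIPP spindle %.1f, ripple %.1f",
                  dens[1], dens[2], dens[3]))
  jsonlite::write_json(list(scores = scores, density_per_min = as.list(dens)),
                       file.path(out, paste0(nm, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
message("wrote ", out)
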