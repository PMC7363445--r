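#!/usr/bin/env Rscript
# Generate the two canonical synthetic nights and write them to disk in the
# exchange formats (EDF + plain-text hypnogram + TSV/JSON ground truth):
#  - a 30-min detector-validation night (dense events, for recall/precision
#    scoring against ground truth), and
#  - a 45-min "coupling night" at patient-like ripple density with
#    NC-leads-HIPP spindle coupling around ripples, which carries the
#    surrogate-control and connectivity analyses downstream.

suppressMessages(library(ripplelock))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating the detector-validation night (30 min) ...")
det <- generate_recording(sim_config(
  duration_s = 1800, seed = 1,
  artifact_injection = list(n_amplitude = 2, n_gradient = 3, n_hf = 2)))
write_simulation(det, file.path(out, "detection_night"))

message("simulating the coupling night (45 min) ...")
cpl <- generate_recording(sim_config_coupling(seed = 2))
write_simulation(cpl, file.path(out, "coupling_night"))

for (nm in c("detection_night", "coupling_night")) {
  ev <- read_events(file.path(out, nm, "truth_events.tsv"))
  message(sprintf(
    "%s: %d injected events (%d NC spindles, %d HIPP spindles, %d ripples)",
    nm, nrow(ev), sum(ev$channel == "NC" & ev$kind == "spindle"),
    sum(ev$channel == "HIPP" & ev$kind == "spindle"),
    sum(ev$kind == "ripple")))
}
message("wrote ", out)
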