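---
title: "Ripple-locked hippocampal-neocortical spindle coupling: methods"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Ripple-locked hippocampal-neocortical spindle coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ripplelock)
```

# What this package computes

During non-rapid-eye-movement (NREM) sleep, hippocampal sharp-wave ripples
(brief 80--120 Hz bursts riding on a ~3 Hz sharp wave) co-occur with
thalamocortical sleep spindles (12--16 Hz, 0.5--2 s). `ripplelock`
implements the complete analysis chain used to quantify whether, and in
which direction, the neocortex (NC, a scalp channel) and the hippocampus
(HIPP, a depth channel) communicate in the spindle band around individual
ripples:

1. automated artifact rejection (three detectors, padding, short-gap rule);
2. discrete spindle and ripple detection by band-limited RMS-envelope
   thresholding with duration, cycle, and frequency-profile criteria;
3. matched, ripple-free surrogate ("control") events -- 100 sets, one
   surrogate per empirical ripple;
4. Morlet-wavelet time-frequency decomposition with an adaptive cycle rule;
5. ripple-locked power contrasts against the averaged controls, corrected
   by cluster-based permutation statistics;
6. trial-ensemble spectral coherence, phase-locking value (PLV),
   orthogonalized power correlation, and non-parametric partial directed
   coherence (PDC) with z-statistics against the 100 control sets;
7. peri-ripple histograms of spindle onsets, ripple-duration tertile
   splits, and duration--power correlations.

Because depth recordings are not redistributable at will, the package
ships a synthetic two-channel sleep-EEG generator with full ground truth,
and every stage is validated against that ground truth. The synthetic
data module is first-class, tested code: its output defines the study
conditions under which the pipeline is verified.

# Event detection

Both detectors share one algorithm and differ only in parameters
(`detector_params()`):

| parameter | spindles | ripples |
|---|---|---|
| band | 12--16 Hz | 80--120 Hz |
| RMS window / smoothing | 200 ms / 200 ms | 20 ms / 20 ms |
| detection threshold | mean + 1.25 SD | mean + 2.5 SD |
| upper cut-off | mean + 5 SD | mean + 9 SD |
| duration | 0.4--3 s | 38--500 ms |
| raw cycles | -- | >= 3 |
| profile TFR | 9--19 Hz, +/-750 ms | 65--135 Hz, +/-100 ms |

The signal is band-passed, a centered moving RMS is computed and smoothed
once more with the same window, and threshold statistics (mean, SD) are
taken across **all artifact-free NREM samples**. Candidate events are
maximal supra-threshold runs within the duration bounds; candidates whose
envelope exceeds the upper cut-off anywhere are discarded (the
conservative reading of "time points exceeding an upper threshold were
excluded": the upper bound is an artifact guard, and a partially
artifactual event is not trustworthy). Spindle peaks sit on the deepest
filtered trough, ripple peaks on the largest positive filtered peak; the
38 ms ripple minimum corresponds to 3 cycles at 80 Hz.

Because both thresholds are derived from the data, the detected event set
is invariant under positive rescaling of the signal -- a property the test
suite asserts.

**Raw-cycle criterion.** "At least three cycles in the raw signal" is
ill-posed under 1/f noise, so it is operationalized on a broadly filtered
trace: half-waves are delimited by zero crossings and count only if their
extremum reaches 25% of the event's maximum amplitude; a cycle is two
half-waves. For ripples the broad trace is 30--300 Hz: every genuine
ripple rides a ~3 Hz sharp wave whose amplitude would otherwise remove the
zero crossings entirely. For spindles the trace is 0.3--300 Hz. Both
bands are configurable (`cycle_band_hz`).

**Frequency-profile filter.** For each candidate, a fine-grained wavelet
profile is computed around the peak (2 ms steps), its magnitude averaged
over the central span, and the event is kept only if the **profile
maximum** lies inside the band of interest and is a peak with prominence
of at least 20% of that maximum. We deliberately bind the rule to the
profile maximum (not to any in-band local peak): broadband transients --
interictal-like spikes and their filter ringing, the classic source of
"false ripples" -- produce profiles whose maximum sits below the band or
lacks prominence, and are rejected. Peak prominence uses the standard
definition (height above the higher of the two bounding valleys); other
software may resolve plateau/tie cases differently, so exact equivalence
with any specific implementation is not guaranteed.

# Artifact rejection

Three automated detectors run per channel, with data-derived thresholds
computed separately per sleep stage (unscored samples fall back to global
statistics):

* **amplitude**: |filtered signal| > 750 uV;
* **gradient**: sample-to-sample difference outside median +/- 6 IQR
  (two-sided -- the rule names a symmetric interval, and downward steps are
  as artifactual as upward ones);
* **high-frequency bursts**: 150 Hz high-passed, 100 ms moving RMS above
  median + 4 IQR for at least 100 ms.

All flagged samples are padded by +/-250 ms, and artifact-free gaps
shorter than 3 s are themselves marked (provenance `short_gap`).

Two numerical choices matter here. First, the 0.3--150 Hz pre-filter for
the amplitude and gradient detectors uses a **causal first-order
(6 dB/octave) high-pass** at 0.3 Hz plus a zero-phase 150 Hz low-pass.
The gentle causal low edge mirrors the acquisition chains these uV
thresholds were calibrated on and preserves the onset amplitude of
step-like excursions; a sharp zero-phase 0.3 Hz filter would attenuate a
1-s 800 uV excursion to ~430 uV and silently defeat the +/-750 uV rule.
Second, a centered RMS window smears a burst by up to one window length,
so the >=100 ms run criterion for high-frequency bursts is applied after
correcting the run length by 0.75 windows; without this, a 50 ms burst
passes a naive 100 ms run test. Degenerate cases (constant-derivative
signals, numerically silent channels) produce no flags: thresholds that
fall below quantization scale (0.01 uV for gradients, 0.5 uV RMS for
bursts) are treated as "nothing to detect".

# Matched ripple-free control events

For every empirical ripple, 100 surrogate intervals of **identical
duration** are drawn whose spans, padded by 1.5 s on both sides, lie
entirely in artifact-free NREM and contain no detected ripple. Candidate
centers are drawn from a Gaussian (SD 200 s; the dispersion is not fixed
by convention, so it is a configurable package default) centered on the
ripple peak and truncated at +/-10 min, so surrogates share the slow
nonstationarity of their ripple's neighbourhood. The Gaussian weight
applies to the surrogate **center** offset. Once assigned, a surrogate's
core interval is excluded from all later draws (across sets); if a
ripple's window is exhausted the window widens in 5-min steps with a
warning. Sampling is by rejection, which reproduces the truncated-Gaussian
weighting exactly on the eligible set; a Kolmogorov-Smirnov test in the
suite confirms it. `audit_control_sets()` re-verifies every constraint
after the fact, and the acceptance run requires zero violations.

"Ripple-free" is asserted against the final (post-filter) detected ripple
list; a stricter variant against pre-filter candidates would only shrink
the eligible pool.

Power comparisons average the 100 surrogate TFRs per ripple, giving one
paired control per event (paired t-tests); connectivity metrics, which
are defined across events, instead use the 100 per-set values as the
null distribution for z-statistics.

# Wavelet analysis

Time-frequency decomposition uses L2-normalized complex Morlet wavelets
on a 1--20 Hz grid (0.5 Hz steps) with 20 ms output resolution. The cycle
count is adaptive: `max(5, ceiling(f/2))` for f >= 5 Hz, and 2/3/4 cycles
below 5 Hz (up to 2, 3.5 and 5 Hz respectively) so slow wavelets keep
usable support. The Gaussian SD is `sigma_t = n_cycles / (pi * f)`; over
the 12--16 Hz spindle grid the mean temporal resolution is 0.167 s.
Wavelet support is truncated at 3 sigma_t; epochs are cut at +/-3 s around
lock points so every cell of the +/-1 s analysis window has full support
even at 1 Hz. Cells without full support are marked invalid (NA), never
zero-padded -- zero-padding would bias power toward zero exactly where
stage transitions make estimates precious.

The main TFR runs on data decimated to 100 Hz (the grid tops out at
20 Hz); the event-profile TFRs run at the native rate. Power is only ever
used in ratios, contrasts, or rank statistics, so the absolute scale of
the L2-normalized coefficients is immaterial.

# Connectivity

All trial-ensemble metrics operate on aligned TFR stacks
(event x frequency x time):

* **coherence** `|<X conj(Y)>| / sqrt(<|X|^2><|Y|^2>)` (magnitude
  coherence, not squared, matching the convention of the framework the
  analysis mirrors; both conventions are monotonically related);
* **PLV** -- magnitude of the mean unit phasor of the phase difference;
* **orthogonalized power correlation** -- each channel is orthogonalized
  on the other (`imag(Y conj(X)/|X|)`) before correlating power across
  events, and the two directed maps are averaged. This removes the
  instantaneously in-phase component and with it volume-conduction and
  common-reference artifacts; the suite verifies that adding an identical
  common signal to both channels inflates the raw power correlation but
  leaves the orthogonalized one in place. Collinear cells (residual below
  numerical scale) are invalid.

The scalar statistic of interest is the mean over the joint spindle
window, -220 to +460 ms x 11.5--18 Hz, z-scored against the 100 control
sets (significance |z| > 1.96); the 12--16 Hz band average gives the
z time course.

**Partial directed coherence.** Directionality uses the non-parametric
route: on sliding 512 ms windows (20 ms steps, epochs decimated to
250 Hz so a window is exactly 128 samples), the demeaned, Hann-tapered
trial-averaged cross-spectral matrix is factorized with the Wilson-Burg
algorithm (tolerance 1e-9, at most 200 iterations; non-converged windows
are marked invalid) into a minimum-phase transfer function and noise
covariance. The inverse transfer function plays the role of the spectral
autoregressive representation, and PDC is its column-wise (outflow)
normalization, so for data generated by a true VAR model the estimate
converges to the analytic PDC of the generating coefficients -- the test
suite verifies this against both the closed-form PDC and an independent
least-squares VAR fit. Within-window spectra use the DFT rather than the
Morlet coefficients: Wilson-Burg factorization needs the spectral matrix
on a uniform grid from DC to Nyquist, which a 1--20 Hz wavelet grid cannot
supply; everything else stays on the wavelet framework. The 12--16 Hz PDC
band means for each direction are z-scored per time bin against the
control sets and subtracted (NC driving HIPP minus HIPP driving NC);
positive values indicate neocortical drive. Because directionality is
meaningless without coupling, the z-difference is reported only at time
bins with significant spectral coherence (the unmasked trace is kept as an
attribute). The estimator floor of about 30 trials triggers a warning,
not an error.

A known small-sample property worth stating: in the **non-driven**
direction the PDC magnitude carries a positive bias of order
`sqrt(pi/(4 n_trials))` (the expected magnitude of a complex-Gaussian
average). Validation holds the driven direction to Monte-Carlo spread and
allows the null direction twice this theoretical bias.

# Statistics

* `z_vs_controls()` -- the z of an empirical scalar against the control
  distribution; two-sided p from the normal CDF.
* `cluster_permutation()` -- per-cell paired t (event vs averaged
  control), two-sided cell threshold at alpha = 0.05, 4-connected
  clusters in the frequency x time grid, cluster mass = summed t, null by
  random within-pair sign flips (1000 by default; the correction quality,
  not validity, depends on the count), corrected p = proportion of
  permutation maximum masses at least the observed mass. Family-wise
  error calibration runs in the acceptance suite (200 null simulations on
  a reduced grid, 15 pairs, 200 permutations each -- sizes chosen to make
  the calibration a routine part of every run).
* `spindle_onset_histogram()` -- 50 ms bins of spindle onsets within
  +/-0.5 s of ripple peaks, normalized by the total number of detected
  spindle onsets x 100; per-bin z against the control-locked histograms,
  one-sided significance at z > 1.96 (enrichment is the hypothesis; the
  printed 1.96 cut-off is kept).
* `tertile_split()` -- per-patient interpolated quantiles at 1/3 and 2/3;
  boundary ties fall into the discarded middle tertile, keeping the
  short/long groups conservative.
* `long_vs_short_power_test()` -- one-sided pooled-variance t-test.
* `duration_power_correlation()` -- per-patient Spearman r between ripple
  duration and event power, Fisher z (clipped at |r| = 1 - 1e-12; with
  identical correlations in every patient the t statistic degenerates and
  significance is decided by the common sign), one-sample t across
  patients.

# The synthetic phantom: what it emulates, and what it does not

`sim_config()` builds a statistical phantom, not a biophysical model:

* background: 1/f noise (exponent 1, 15 uV RMS) plus a broadband floor
  (4 uV), slowly amplitude-modulated (depth 0.6, ~0.03 Hz), with an
  NREM-gated 0.8 Hz slow-oscillation component (20 uV);
* HIPP additionally carries a flat 60--250 Hz floor (3 uV) and
  **interictal-like spikes** (60/min, ~18 uV, 3 ms biphasic) -- sharp
  broadband transients whose band-pass ringing inflates the ripple-band
  RMS statistics exactly as interictal discharges do in patient data;
* spindles: Hann-enveloped sinusoids (13.5 Hz, 0.8--1.8 s, ~27 uV,
  log-normal amplitude spread) at 5/min per channel;
* ripples: Gaussian-enveloped 90 Hz bursts on a single 3 Hz sharp-wave
  cycle (negative half-wave, positive rebound), placed by a dead-time
  Poisson process (minimum gap keeps adjacent coupled spindles from
  merging during detection);
* coupling: with probability 0.8 a ripple is preceded by spindles in both
  channels, the NC onset 225 ms and the HIPP onset 75 ms before the
  ripple peak (jitter SD 15 ms, truncated at 3 SD). The HIPP spindle's
  carrier is a mixture (`direction_mix`, default 0.8) of the NC carrier
  delayed by 20 ms and an independent carrier under HIPP's own envelope,
  which yields a ground-truth NC-to-HIPP direction while keeping the two
  regional onset lags independent parameters;
* `duration_effect` scales coupled-spindle amplitude with relative ripple
  duration, `1 + slope * (dur - median)/median`;
* injected artifacts per class: boxcar excursions (900 uV), decaying
  2000-to-400 uV steps, and flat-envelope 200 Hz bursts (120 uV, 150 ms).

Two deliberate departures from patient statistics are worth spelling out.
First, the default validation night uses a ripple density of 8/min --
roughly 6x the patient average. The detection thresholds are moments of
the data themselves, and on a 30-min stationary phantom a realistic event
density leaves the band-RMS SD so small that the upper cut-off (mean +
9 SD) would sit *below* genuine ripple envelopes while the lower threshold
would sit low enough to admit a steady stream of narrowband noise runs.
Real recordings escape this bind through heavy-tailed in-band background
(ongoing gamma, interictal activity) accumulated over whole nights. On a
short phantom, raising event occupancy (together with the spike
component) is the transparent way to give the thresholds the variance
they implicitly assume; amplitudes were then chosen once, by parameter
sweep, for near-ceiling detector recall, and frozen. Second, the
surrogate machinery needs the opposite regime: 100 non-overlapping
duration-matched cores per ripple simply do not fit into a 30-min night
at 8/min. The canonical **coupling night** (`sim_config_coupling()`,
45 min at 2.2 ripples/min) therefore carries the control, connectivity,
and directionality analyses, at a surrogate-core occupancy near 25% of
the clean NREM pool.

What passing tests on the phantom do **not** show about real data: the
phantom's events are strictly band-limited with known envelopes, its
false positives come from well-behaved noise rather than pathology, its
spindle "onsets" are exact envelope starts (threshold detectors register
onsets with a systematic delay of roughly +0.2 s for Hann envelopes --
the peri-event histograms on detected events inherit that shift while
preserving the NC-before-HIPP order, which is why lag-recovery checks use
the ground-truth lists), and detected short "ripples" are enriched in
false positives that lack coupled spindles, so a positive duration-power
association exists even at `duration_effect = 0`. Conclusions about
effect sizes on patient data cannot be read off the phantom.

# Reproducibility and problem sizes

Every stochastic stage takes a seed, and the whole chain is bit-for-bit
deterministic given one. The canonical runs used throughout the scripts
and the acceptance suite are: the 30-min detection night, the 45-min
coupling night with 100 control sets (the long stage: every set receives
a full wavelet and PDC pass; minutes of compute), 200-simulation
permutation calibration on a 12 x 20 grid with 15 pairs, and four 10-min
"patients" for the duration analyses. These sizes are the package's
standing choices for routine validation; all of them scale up by changing
one configuration argument.

# Known limitations

* Two channels only; no conditional or multivariate PDC.
* The hypnogram is an input (no automatic staging), and inputs are
  assumed pre-referenced; montage re-referencing is out of scope.
* The EDF reader/writer covers the plain 16-bit EDF subset used here
  (uniform sampling rate, 1 s records), not EDF+ annotations.
* Peak-prominence conventions at plateaus may differ from other software.
* The phantom's detection-threshold regime is calibrated, not emergent;
  see above.
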