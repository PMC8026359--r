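---
title: "Methods: sulcus-aligned motor mapping, the rostrality index, and the calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sulcus-aligned motor mapping, the rostrality index, and the calibrated synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knobmap)
```

knobmap implements the analysis chain of a multimodal mapping study of the
precentral motor hand knob — the knob-shaped part of the precentral gyrus
that houses the primary motor hand area (M1) and the caudal dorsal premotor
cortex (PMd). The scientific question the chain serves: does the cortical
myelin content of the hand knob (indexed by the quantitative-MRI
longitudinal relaxation rate R1 = 1/T1) explain between-subject differences
in where TMS best excites the corticomotor output, how long the
corticomotor conduction takes, how strongly the region activates during a
paced finger task, and how precisely the fingers keep the pace?

This vignette documents the models, the parameter choices, and the design
decisions behind each module, and states what the validation suite does and
does not demonstrate.

## 1. Sulcus-aligned grid geometry

Standard grid mapping keeps the coil orientation fixed, so the induced
current hits the gyral crown at varying angles. The sulcus-aligned
alternative follows the individual gyrus-sulcus border: line 1 of the grid
lies on a digitized border polyline, lines 2-5 are offset anteriorly in
5 mm steps, and every line holds 7 targets at 5 mm arc-length spacing
(35 sites). At each site the coil orientation — the direction of the
effective, second-phase induced current — is the local *anterior in-plane
normal*: the unit vector perpendicular to the local line tangent within the
tangent-anterior plane, pointing towards larger y (anterior in the MNI-like
frame used throughout; x lateral, z superior; continuous millimetres, never
voxel indices).

Numerical choices:

* Arc-length resampling interpolates linearly between polyline vertices.
* Tangents are central differences at interior vertices and second-order
  one-sided differences at the endpoints. Offsets are computed on a
  50-fold oversampled resampling of the border, because offsetting the
  7 target points directly would tilt the endpoint normals by half a
  segment angle and distort the outer lines.
* The interline spacing is not prescribed by the mapping protocol we
  emulate; the default of 5 mm makes the footprint roughly 20 x 30 mm,
  matching the region-of-interest extent used for the MRI readouts.
* On curved borders the anterior offset necessarily shortens (concave
  side) or lengthens (convex side) the outer lines; within one line the
  spacing stays uniform to well under 2% provided the curvature radius is
  large relative to the total offset. The grid builder is exact for
  straight borders.
* Equivariance: rotating the input curve about the anterior axis and/or
  translating it moves all sites and orientations rigidly. General
  rotations do *not* commute with grid construction, because "anterior"
  is a fixed axis of the coordinate frame — by design, since coil
  orientations are anatomically referenced.

## 2. MEP extraction

EMG is stimulus-locked, 10 kHz, spanning -100 to +60 ms; hardware is
assumed to have bandpass filtered the signal (20-3000 Hz), so no filtering
is applied here.

* **Artifact screen** (surrogate for visual trial rejection): a trial is
  invalid when the RMS of the -100..0 ms baseline exceeds 0.02 mV.
  At the default background noise (SD 0.01 mV) clean trials are rejected
  at well under 1%.
* **Amplitude**: peak-to-peak (max minus min) of the 10-40 ms window.
* **Latency** (surrogate for visual onset reading): earliest time in
  10-40 ms at which the rectified, baseline-corrected signal exceeds
  3 baseline SDs continuously for 0.5 ms. All three parameters are
  exposed. The rule has a *systematic detection delay*: with the 8 ms
  biphasic template (below) a 1 mV MEP needs ~0.76 ms to clear
  3 x 0.01 mV, and the delay shrinks slowly with amplitude. Its precision
  is high (SD ~0.08 ms at that operating point). We deliberately do not
  subtract a template-specific correction — that would be circular with
  the generator — and instead document the bias and let the validation
  measure the net effect (Section 6).
* **Excitability map and hotspot**: per-site mean amplitude over valid
  trials; sites with zero valid trials are flagged, excluded, and warned
  about. The hotspot is the unflagged site with the largest mean; exact
  ties break towards the posterior then medial site and are logged
  (measure-zero under noise). The shortest latency is the minimum valid
  per-trial latency among the hotspot's trials — a per-trial reading of
  what a human rater does on superimposed sweeps.
* **Resting motor threshold**: adaptive maximum-likelihood threshold
  hunting (PEST family). A logistic recruitment curve with fixed slope
  (2% MSO) is refit over a 1% MSO grid after every response; the next
  stimulus is delivered at the current ML threshold; 20 trials, start at
  50% MSO. These parameters follow common adaptive-threshold practice.
  Estimates within one grid step of the boundary (e.g. after an all-yes
  or all-no run) are flagged. Against a deterministic step responder the
  estimate lands within 1% MSO; against a stochastic logistic responder
  the mean absolute error is below 2% MSO.

## 3. Spatiotemporal rostrality index

Per muscle and subject the index multiplies two min-max-normalized
quantities, each scaled across the whole cohort within muscle:

$$\mathrm{index}_i \;=\; \frac{y_i - \min_j y_j}{\max_j y_j - \min_j y_j}
\;\times\; \frac{\ell_i - \min_j \ell_j}{\max_j \ell_j - \min_j \ell_j},$$

where $y_i$ is the hotspot y-coordinate (anterior = larger) and $\ell_i$
the shortest MEP latency. A subject holding both cohort maxima scores
exactly 1, both minima exactly 0. Normalization is never per-group; when a
cohort is degenerate (identical extremes) the index is undefined and the
function raises instead of returning 0 or 1 silently. Subjects whose
hotspot lies on grid lines 1-2 (posterior lip, near the central sulcus)
form the *caudal* group, lines 3-5 (crown) the *rostral* group.

The index is invariant under affine transforms applied uniformly to the
y-coordinates or latencies, and monotone in both inputs at fixed cohort
extremes. Note one consequence of the product form: even under perfect
(noise-free) couplings the index is a *nonlinear* monotone function of the
underlying trait, so its correlation with a linear readout is slightly
below 1 — this matters for calibration (Section 5).

## 4. Movement timing from force traces

The visuomotor synchronization task paces abduction presses of the index
or little finger at 1 Hz: movement blocks of 10 cues alternate with rest
blocks (18 movement blocks per finger). The strain-gauge voltage (0-2.5 V,
500 Hz) is analysed as follows:

* **Peak detection**: local maxima at or above 0.6 V, with topographic
  prominence of at least one third of the trace maximum (height above the
  higher of the two flanking minima bounding the peak's basin), separated
  by at least 0.4 s (the higher of two close candidates wins). Saturated
  plateaus — the sensor clips at 2.5 V, and subjects routinely exceed the
  range — are assigned their plateau midpoint. The implementation computes
  prominences from candidate peaks and inter-candidate valley minima
  (O(n + k^2)); the test suite proves it identical to an exhaustive
  per-sample oracle on random traces.
* **Interval CV**: successive peak-time differences, pooled within
  movement blocks and never across rest gaps (a crossed boundary would
  inject an artifactual multi-second interval); sample SD (n-1); CV =
  SD/mean. Fewer than two intervals yields a flagged, absent result.

## 5. The synthetic cohort generator

No raw data are available for this kind of study, so the generator is the
package's test bed: it emulates the *statistical structure* the analysis
assumes, calibrated to published summary statistics, and every analysis
module must recover the calibration from raw simulated data.

**Latent-trait model.** One standard-normal myelin trait $z_1$ per subject
drives every coupled readout via $z_2 = \rho z_1 + \sqrt{1-\rho^2}\,
\varepsilon$:

* Regional R1: caudal mean 796.48, rostral 756.75 ms$^{-1}$, shared
  between-subject SD 39.8 ms$^{-1}$ (printed SEMs times $\sqrt{20}$). A
  subject-specific gradient term (SD 35.05 ms$^{-1}$, back-calculated from
  the published paired ROI contrast t(19) = 5.069) is added to the caudal
  and subtracted from the rostral ROI, so it cancels exactly in the
  whole-knob mean that enters all correlations. Four of 24 subjects lose
  their R1 to (simulated) motion artifacts.
* Hotspot y: mean -16.6 mm, SD 4.9 mm, driven by a rostrality driver with
  $\rho = 0.805$ (see calibration below). Shortest latency follows y
  linearly: intercept 22.6 ms (index-finger muscle; 22.9 little-finger),
  slope and residual SD derived from the target y-latency correlation
  0.697 and total latency SD 1.47 ms. The little-finger hotspot tracks
  the index-finger one with 2 mm y-jitter and a 3.3 mm medial shift.
* BOLD effect sizes couple at $\rho$ = 0.748 (little) / 0.659 (index);
  intermovement CV at $\rho$ = -0.684 / -0.619. CV marginals are not
  published; mean 0.06 and between-subject SD 0.02 are typical for 1 Hz
  paced tapping and were fixed once.
* Hotspot amplitude: lognormal across subjects, means 1.11 / 0.50 mV,
  between-subject CV 0.75 (SEM-derived); RMT: mean 58.1, SD 10.8% MSO.

**Why $\rho_{R1,\mathrm{rostrality}} = 0.805$ and not 0.699.** The
published value 0.699 is the correlation of R1 with the *product-form
index*, not with the latent driver. Because the product of two min-max
normalized, imperfectly correlated components attenuates the driver
correlation (and small-sample r is itself biased towards zero), setting
the driver correlation to 0.699 would make cohorts of n = 20 recover only
~0.60. The default 0.805 was derived once by Monte Carlo (40,000 synthetic
cohorts of n = 20, solving for the driver value whose mean recovered
sample correlation is 0.699) and then frozen. The y-latency, BOLD and CV
couplings need no such correction: they enter the battery linearly, and
their small-sample attenuation stays well inside the tolerance.

**EMG sessions.** Expected site amplitude is an isotropic Gaussian bump of
width 7 mm centred on the subject's hotspot; trial amplitudes are
lognormal around the site mean (CV 0.4); the waveform is a biphasic
Hanning-windowed 8 ms sine scaled to the trial's peak-to-peak amplitude on
the discrete sample grid (so noise-free extraction is exact); the onset is
the subject's latency plus Normal(0, 0.3 ms) trial jitter; background
noise is white Gaussian, SD 0.01 mV. With 20 trials per site this makes
hotspot detection reliable but not trivial: the exact generating site wins
~91% of sessions, and localization lands within one 5 mm grid step of the
true hotspot in ~98%.

**Force traces.** One raised-cosine pulse (0.4 s) per cue, centre jittered
by Normal(0, cv$/\sqrt{2}$) s so that intervals have CV $\approx$ cv;
amplitudes Normal(2.2, 0.6) V floored at 0.9 V — the floor guarantees
every press clears both the 0.6 V threshold and the worst-case prominence
floor (2.5/3 V), because a missed press would inject a spurious 2 s
interval and the CV is meant to measure timing variability, not detector
misses. The summed trace is clipped to [0, 2.5] V; sensor noise defaults
to zero (the apex of a raised cosine is flat to ~1 mV, so even small noise
would only dither peak times by single samples).

**Determinism.** Every subject, session and trace draws from a substream
seeded by hashing the master seed with stable labels
(`substream_seed(seed, "subject", i)` etc.), so identical seeds give
bit-identical cohorts and adding subjects never perturbs existing ones.

## 6. Cohort statistics and validation design

Pearson correlations (two-sided p from the t transform), Welch tests with
Welch-Satterthwaite degrees of freedom (also available from printed
mean/SD/n summaries), paired t tests, and Bonferroni adjustment with an
explicit family size wrap the corresponding base-R routines behind a
validated interface. The battery has a fixed, documented layout with four
families: y-latency per muscle (m = 2), whole-knob R1 against the six
functional readouts (m = 6), the same readouts against the two sub-ROI R1
means (m = 12), and thickness/curvature specificity controls (m = 4).
R1 rows run on the subjects with valid R1 only; a degenerate column
degrades only its own rows.

Problem sizes used by the validation suite and the acceptance script,
chosen to put Monte-Carlo error well inside each tolerance:

* 200 record-level cohorts of n = 20 (force traces simulated and
  re-analysed for the CV) for the correlation-recovery checks;
* 100 EMG-level cohorts of n = 24 (FDI muscle, 700 trials each) for the
  amplitude/latency marginals;
* 1,000 single sessions for hotspot localization; 10,000 null draws for
  the type-I error of the correlation test; 1,000 runs for the threshold
  estimator; 100 random traces for detector-oracle equivalence.

The latency marginal deserves its honest accounting: the recovered grand
mean (~22.86 ms against the 22.6 ms calibration) is the net of two
opposing biases — taking the minimum of 20 jittered trials pulls ~0.6 ms
down, the onset rule's detection delay pushes ~0.85 ms up. Both are
properties of the documented trial model and onset rule, not tuning knobs.

## 7. What passing tests do and do not show

The generator reproduces the *second-order structure* of the study —
means, between-subject SDs, and the printed pairwise correlations — under
a single-factor Gaussian model. It does not emulate: real EMG spectra or
artifact morphology (only white noise and a stylized biphasic template);
anisotropic or multi-peaked excitability surfaces; E-field physics or
coil-scalp geometry; non-Gaussian trait distributions; learning or fatigue
across a session; or any vertex-level imaging. Recovery of the calibrated
values therefore validates the *pipeline* (geometry, extraction, indexing,
statistics) — it is not evidence about the biology, and thresholds tuned
here (artifact limit, latency rule) would need re-validation against
expert readings before use on real recordings.
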