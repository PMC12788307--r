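---
title: "Methods: band power, imaginary-coherence networks and age-adjusted group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, imaginary-coherence networks and age-adjusted group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eegfc` implements a complete analysis chain for comparing task-block scalp
EEG between patients with functional constipation and healthy controls:
relative band power by cortical lobe, functional connectivity as the
imaginary part of coherency, sparsity-thresholded binary brain networks
summarized by AUC topological features, and age-adjusted ANCOVA group
statistics with Benjamini–Hochberg FDR correction. Because clinical
recordings of this kind are not publicly deposited, the package also ships
a synthetic-cohort generator with exactly the statistical structure the
analysis assumes, so that every stage — and the pipeline end to end — is
testable from code alone. This vignette documents the models, the knobs
that matter, and the design decisions taken where the methodology leaves
room.

## The analysis model

**Relative band power.** For each channel, the Welch power spectral
density $P(f)$ is integrated over the five canonical bands
(delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz) and
normalized by the integral over the full 0.5–45 Hz range:

$$\mathrm{RP}_b = \frac{\int_{\Omega_b} P(f)\,df}{\int_{0.5}^{45} P(f)\,df}.$$

Integration uses the trapezoid rule on the PSD grid; a grid point shared
by two bands contributes half its weight to each, so the five fractions
sum to one by construction. Relative (rather than absolute) power makes
the measure invariant to per-channel amplitude scaling, which is why
regional aggregation simply averages the member channels' fractions.

**Connectivity.** For channels $x, y$ the coherency is
$C_{xy}(f) = S_{xy}(f) / \sqrt{S_{xx}(f) S_{yy}(f)}$, estimated from
Welch-averaged cross-spectra that share the PSD's segmentation. The
band-level edge weight is the band average of $|\mathrm{Im}\,C_{xy}(f)|$.
The imaginary part is blind to zero-lag coupling, the signature of volume
conduction: mixing independent sources through any instantaneous real
matrix leaves the imaginary part at its estimation noise floor, a property
the test suite checks directly. The absolute value prevents opposite-signed
bins from cancelling; a `signed = TRUE` flag exposes the signed average for
users who want directionality of the lag.

**Network topology.** Each connectivity matrix is binarized by
proportional thresholding — keeping the $\mathrm{round}(s\,n(n-1)/2)$
strongest edges at sparsity $s \in \{0.10, 0.15, 0.20, 0.25, 0.30\}$ —
and three global metrics are computed on each binary graph: global
efficiency (mean inverse shortest-path length, disconnected pairs
contributing zero), average local efficiency (mean over nodes of the
global efficiency of the open neighborhood subgraph), and the average
clustering coefficient. The trapezoid integral of each metric's
trajectory across the sparsity grid (its AUC, at most 0.2 over a 0.2-wide
grid for metrics bounded by 1) is the threshold-independent feature
carried into statistics. Binary rather than weighted graphs follow the
proportional-threshold convention of the functional-connectome
literature; a weighted analysis can be built from the exported matrices
if desired. Rounding uses R's round-half-to-even; ties at the cutoff
weight are broken by ascending (row, column) index so results are
deterministic.

**Group statistics.** Each feature cell is compared between groups with
an ANCOVA — a linear model `value ~ group + age` — testing the group term
with a partial F on $(1, n-3)$ degrees of freedom. Age is included
because uneven age distributions are a realistic confound in clinical
cohorts; when the covariate is degenerate the model falls back to one-way
ANOVA with a warning. P-values are BH-FDR adjusted within each
(task, band) family across the five lobes. Network AUC features are
reported with raw p-values by default (each metric forming its own
family), mirroring the asymmetric reporting convention for these two
feature classes; `fdr_network = TRUE` applies FDR there too. Effect sizes
are Cohen's d with the pooled SD and a patient-minus-control sign
convention; $|d| > 0.5$ flags a medium effect. The significance and
medium-effect criteria are always reported as separate columns and never
merged.

## The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. Each
channel is the sum of

* a $1/f$ background: frequency-domain shaped Gaussian noise with power
  $\propto f^{-e}$ (default exponent $e = 1$, floored below 0.5 Hz),
  scaled to 10 µV RMS — a realistic resting scalp amplitude;
* per band and lobe, a band-limited oscillator built in the frequency
  domain as a mixture of a *region-shared* source and channel-private
  noise, with weights $\sqrt{q}$ and $\sqrt{1-q}$ for shared fraction
  $q$ (default 0.6). Each channel applies a uniform random phase lag to
  the shared source; non-zero lags are what make the imaginary part of
  coherency non-zero, so $q$ is effectively the imaginary-coherence dial;
* optional artifacts: whole-channel flatlines, transient single-channel
  flatline segments, and stereotyped biphasic blinks weighted by a
  frontal spatial profile (so that the template-based artifact-removal
  stage has something physically plausible to find).

Oscillator RMS amplitudes come from a (group × lobe × task × band) table.
The defaults emulate a canonical resting spectrum (delta 4, theta 3,
alpha 4 — raised to 6 µV over parietal/occipital for posterior alpha
dominance — beta 2, gamma 1 µV RMS), identical in both groups; group
differences are always injected explicitly. Between-subject variability
is a per-subject, per-band log-normal amplitude multiplier
(`subject_sd`, default 0.25 on the log scale), which is what gives
group-level effect sizes a finite denominator. Components are normalized
to their *expected* RMS so the whole recording is realized by a single
inverse FFT per task block; realized band power therefore fluctuates
around its target with the usual chi-squared concentration, exactly as an
estimator would see on real data.

Cohort defaults follow the modelled study: 21 patients and 37 controls,
ages uniform on 23–80 years, a 64-channel 10-10 montage at 250 Hz, and a
task schedule of resting 420 s, cognitive 160 s, imagery blocks 30 s and
simulated strain blocks 250 s. The strain blocks are described as five
hold/relax cycles; because the block length and the quoted cycle timing
(5 s hold + 10 s relax) are not mutually consistent, the generator keeps
the 250 s total and exposes `cycle_timing` in the configuration rather
than guessing. An `age_confound` switch draws patient ages from the upper
half of their range, for exercising the ANCOVA adjustment.

What the generator does *not* emulate: biophysical forward modelling
(head geometry, dipole sources), heart/muscle artifacts, and
nonstationarity beyond block-level gain changes. Passing tests therefore
demonstrate that the analysis recovers what it claims from data with the
assumed statistical structure — not that clinical recordings have that
structure.

**Effect calibration.** `calibrate_effect()` finds the patient/control
amplitude ratio whose relative-power Cohen's d matches a target, by
bisection on the log-ratio against pilot simulations. Pilot noise is the
practical obstacle: at realistic pilot sizes the sampling error of d
(≈ $\sqrt{2/n}$) would swamp the search. Two variance-reduction choices
fix this without changing the estimand: pilots are simulated *pairwise*
(each virtual patient shares its control twin's multipliers and noise
realization, differing only in the candidate ratio), and only the target
lobe's channels are generated, since relative power is a per-channel
quantity. Defaults: 60 pilot pairs, 20 s blocks, tolerance ±0.15 on d,
12 bisection iterations.

## Preprocessing

The stage order is fixed: band-pass filter → flatline bad-channel
detection → spherical-spline reconstruction → flatline bad-segment
detection → optional template-based artifact removal.

* **Filter:** 4th-order Butterworth band-pass 0.5–45 Hz applied forward
  and backward (zero-phase, preserving the phase relations coherence
  depends on), on de-meaned data with odd-reflection padding of
  `sampling_rate / low` samples so the slow corner's transient settles.
  The 45 Hz cutoff already excludes 50 Hz line noise, so no notch is
  applied.
* **Flatline rules:** a channel is bad when strictly more than 60% of its
  samples are below 1e-10 µV in magnitude; transient flatlines in any
  channel lasting at least `min_run` (default 0.2 s — the rule needs a
  minimum duration and this is a typical eye-blink-safe choice) become
  bad segments, merged across channels into interval unions. Bad
  segments are treated as exclusion boundaries: spectral estimation uses
  the remaining continuous chunks separately and never concatenates
  across a gap, which would fabricate phase discontinuities.
* **Interpolation:** Perrin-style spherical splines (stiffness order
  m = 4, 50 Legendre terms, ridge 1e-5 — the standard defaults) on an
  idealized unit-sphere 10-10 montage built into the package. Midline
  electrodes sit at 18° steps; lateral electrodes are great-circle
  interpolations between the midline and outer-ring members of their
  row. Good channels are returned bit-identical.
* **Artifact removal:** classifier-based IC labelling cannot be
  reproduced from a description, so the package provides a pluggable
  stage: a deterministic PCA (SVD) unmixing whose components are
  correlated against a caller-supplied artifact template; components
  exceeding the correlation threshold (default 0.8) are zeroed and the
  data re-mixed. A different decomposition or a real classifier can be
  injected through the `decompose` argument. The removed-artifact
  duration (samples where the removed signal's envelope exceeds 10% of
  its peak) feeds the QC report.
* **QC:** three percentages per recording — bad channels over total
  channels; summed per-channel flatline time over channels × duration
  (the per-channel-time convention, so a 6 s flatline in one of 64
  channels of a 600 s recording is 0.0156%); removed-artifact duration
  over recording duration — aggregated to cohort mean ± SD.
* **Resting crop:** only the first 120 s of the resting block is
  analyzed, so every subject contributes equally; shorter recordings are
  used whole with a warning.

## Spectral estimation choices

Welch segments are 2 s with 50% overlap and a Hann taper: 0.5 Hz
resolution is the coarsest grid that still resolves the 0.5 Hz delta
edge, and overlapped Hann segments are the standard bias/variance
compromise. Regional aggregation averages per-channel relative power
rather than averaging spectra first — the former is invariant to
per-channel gain differences; `average_spectra = TRUE` provides the other
order for sensitivity analyses. Topographic maps are numeric grids (not
images): channel values are interpolated with the same spherical-spline
basis used for channel repair, evaluated on a 2-D azimuthal-equidistant
projection of the scalp and masked outside the head circle.

## Numerical and degenerate-input policy

* Zero total power in a channel makes relative power undefined: the
  channel is flagged NA with a warning rather than silently divided.
* Zero auto-spectra inside a band set the affected coherence entries to
  0 with a warning.
* Degenerate ANCOVA designs (constant age, perfect confounding) fall
  back to the group-only model with a warning; a zero-residual fit
  reports p = 0 with a degenerate-fit warning.
* Proportional-threshold ties are index-broken; the empty and complete
  graph limits of all three metrics are covered by tests.
* EDF export quantizes to 16 bits with per-channel symmetric physical
  ranges; round-trip error is bounded by one quantization step.

## Problem sizes used by the packaged checks

The test suite and the reproduction script run entirely on synthetic
data sized for a single CPU: end-to-end effect-recovery uses the full
58-subject cohort with single 30 s task blocks over 20 seeded
replicates, and the null-calibration check uses 1000 simulated
feature families at the stats level (where the full-null family-wise
BH rejection rate has expectation exactly α = 0.05 under independence).
Longer schedules change estimator variance, not the logic being
verified; the configuration exposes every duration if a user wants
study-scale runs.

## Known limitations

* The generator's oscillators are stationary within a block; no
  within-block cycle structure is modelled even for the strain tasks.
* The idealized spherical montage is geometrically regular; interpolation
  accuracy on digitized real-head positions will differ in detail.
* The PCA-plus-template artifact stage is a stand-in with the same
  interface as classifier-based rejection, not a reimplementation of it;
  its removal percentages are comparable in kind but not calibrated to
  clinical values.
* Group inference assumes one value per subject per cell (no repeated
  blocks); modelling within-subject replication would require a mixed
  model, which is out of scope here.
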