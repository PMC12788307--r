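# eegfc

Task-block EEG analysis for functional constipation (FC) cohorts —
relative band power by cortical lobe, imaginary-coherence brain networks
with sparsity-AUC topology, and age-adjusted group statistics — plus a
synthetic-cohort generator so the entire pipeline runs and is tested
without access to clinical recordings.

## Who this is for

Researchers comparing multichannel scalp EEG between a patient group and
controls across task blocks (resting, cognitive, defecation-related
imagery and strain tasks in the modelled design), who need a transparent,
reproducible implementation of the standard regional-power +
functional-connectome analysis chain, and a simulator with controllable
effect sizes for power analysis and method validation.

## The analysis

For each subject, task block and channel, the Welch PSD `P(f)` (2 s Hann
segments, 50% overlap) yields the **relative power** of each canonical
band Ω_b (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–45 Hz):

    RP_b = ∫_{Ω_b} P(f) df / ∫_{0.5}^{45} P(f) df

averaged over the channels of each lobe (frontal / central / temporal /
parietal / occipital). **Connectivity** between channels x, y is the band
mean of |Im C_xy(f)| where `C_xy = S_xy / sqrt(S_xx S_yy)` is the
coherency — the imaginary part is insensitive to zero-lag (volume
conducted) coupling. Each matrix is binarized at sparsity thresholds
s ∈ {0.10, …, 0.30} (keeping the round(s·n(n−1)/2) strongest edges), and
**global efficiency, average local efficiency and average clustering**
are integrated across the sweep (trapezoid AUC) into
threshold-independent features. Every feature cell is compared between
groups with an **ANCOVA** (`value ~ group + age`), Benjamini–Hochberg FDR
applied within each (task, band) family across lobes, and **Cohen's d**
(pooled SD, patient − control sign) with |d| > 0.5 flagged as a medium
effect.

Preprocessing implements 0.5–45 Hz zero-phase Butterworth filtering,
flatline bad-channel (>60% of samples below 1e-10 µV) and bad-segment
detection, Perrin spherical-spline channel reconstruction, a pluggable
template-correlation artifact-removal stage, and QC percentage reports.

See `vignettes/eegfc-methods.Rmd` for the full model description, the
synthetic-data generative model, and every design decision.

## Worked example

Simulate a small cohort with an elevated patient parietal alpha, run the
full pipeline, and inspect the alpha row of the group statistics:

```r
library(eegfc)

cfg <- pipeline_config(
  out_dir = "demo_run",
  simulation = simulation_config(
    n_patients = 6, n_controls = 6, seed = 42,
    task_schedule = data.frame(task = "resting", duration = 60)))
cfg$simulation$band_gains <- set_band_gain(cfg$simulation$band_gains,
  "patient", "parietal", "resting", "alpha", multiply = 1.6)

res <- run_all(cfg)
subset(res$power_stats, band == "alpha")
```

```
      task  band   feature f_stat   p_raw  p_fdr cohens_d medium_effect significant
1  resting alpha   frontal  0.610 0.45490 0.5462    0.244         FALSE       FALSE
6  resting alpha   central  0.393 0.54624 0.5462    0.122         FALSE       FALSE
11 resting alpha  temporal  0.468 0.51135 0.5462    0.240         FALSE       FALSE
16 resting alpha  parietal 13.791 0.00482 0.0241    2.041          TRUE        TRUE
21 resting alpha occipital  0.470 0.51017 0.5462    0.226         FALSE       FALSE
```

The injected effect is recovered exactly where it was planted: the
parietal alpha cell has a large positive Cohen's d (patients above
controls), survives FDR within its (task, band) family
(p_fdr = 0.024 < 0.05), and no other lobe is flagged. `demo_run/`
contains every intermediate table (band power, connectivity-derived
network AUCs, QC report, manifest) as CSV/JSON.

A command-line front end with `simulate`, `preprocess`, `features`,
`stats` and `run-all` subcommands is installed at `inst/cli/eegfc`;
recordings are exchanged as EDF plus a `metadata.csv`.

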