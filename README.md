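# erpmicro

Electrical neuroimaging of two-group ERP studies in R: Global Field Power
statistics, topographic microstate analysis, and distributed source imaging
with cluster-corrected statistical mapping — plus a synthetic-data module
that generates a complete two-group study with a planted early-latency
source difference, so the whole pipeline is testable end to end without
access to raw recordings.

The package is aimed at EEG researchers who want a scripted, reproducible
version of the classic Cartool-style analysis chain for comparing two
groups of subjects (here labeled AP and NAP, for pianists with and without
true absolute pitch) across three stimulus conditions.

## What it computes

**Sensor space.** Zero-phase Butterworth band-pass (0.25–30 Hz) and 50 Hz
notch filtering, decimation 1024 → 256 Hz, ±100 µV threshold artifact
rejection, −200–0 ms baseline correction, common average reference,
spherical-spline interpolation of bad channels, and epoch averaging.

**Global Field Power.** GFP is the spatial standard deviation of the scalp
map at each instant,

    GFP(t) = sqrt( (1/C) Σ_i (u_i(t) − ū(t))² ),

a reference-free scalar of response strength. The group statistic is a
two-tailed pooled-variance t-test on each subject's mean GFP over the
40–80 ms window, with Cohen's d.

**Microstates.** Stage 1 segments the concatenated group grand averages by
a modified k-means: samples are assigned to the template map with maximal
squared spatial correlation, and templates are re-estimated as the first
principal component of their assigned maps. Model order is chosen by the
cross-validation index together with a Krzanowski–Lai criterion on the
within-cluster dispersion curve; maps sharing over 92 % of variance are
merged and segments shorter than 20 ms dissolved. Stage 2 back-fits the
chosen templates into every subject's ERP (winner-take-all spatial
correlation), yielding per-map Duration (ms) and Global Explained Variance
(GEV, %), compared between groups by Kruskal–Wallis tests.

**Sources.** A three-shell concentric spherical head model with an
analytic Legendre-series lead field for 64 scalp electrodes, a ~1000–3005
node cubic solution grid inside the brain shell, and a depth-weighted
minimum-norm (WMN) inverse

    J = W⁻¹ Lᵀ (L W⁻¹ Lᵀ + λI)⁻¹ u,   W = diag(‖l_i‖^{2γ}),

with an optional sLORETA-style variance standardization. Group differences
are mapped node-wise with two-sample t-tests and corrected by a
Monte-Carlo (AlphaSim-style) calibration of the minimum significant
cluster extent on smoothed null fields.

**Behavior.** Signal-detection d′ with the 1/(2N) extreme-rate correction,
Clopper–Pearson binomial intervals and the ≥90 % / ≤65 % CI rule that
classifies pitch-naming scores into AP / NAP / excluded, pooled-variance
t-tests from printed group summaries, and Pearson χ² tests.

## Worked example

Simulate a reduced study (6 vs 6 subjects, 30 epochs per condition,
256 Hz, boost 1.5 on the early left temporo-parietal source for the AP
group) and run every stage:

```r
library(erpmicro)
cfg <- pipeline_config(
  seed = 5,
  sim = sim_spec(n_ap = 6, n_nap = 6, epochs_per_condition = 30,
                 srate = 256),
  montage = montage_biosemi64(), grid_target_count = 1000,
  calib_iters = 1000, preproc = list(notch = NULL, target_srate = NULL))
run_pipeline(cfg, "demo_out")
```

`demo_out/report.txt` then reads:

```
== erpmicro pipeline report ==
seed 5 | 6 AP vs 6 NAP | 30 epochs/condition | boost 1.50

preprocessing: mean %rejected 9.44 (SD 4.10)
GFP 40-80 ms: AP 0.688 vs NAP 0.472 uV | t(10) = 4.08, p = 0.002199, d = 2.36
microstates: q = 4, total GEV 99.3% (max KL within 5% of CV minimum)
  template 1: GEV H = 2.56 p = 0.1093 | Duration H = 0.43 p = 0.5098
  template 2: GEV H = 5.77 p = 0.01631 | Duration H = 0.29 p = 0.5889
  template 3: GEV H = 5.77 p = 0.01631 | Duration H = 0.00 p = 1
  template 4: GEV H = 1.26 p = 0.2623 | Duration H = 0.20 p = 0.6517
sources: 1 cluster(s) at node p <= 0.01, min extent 3
  cluster 1: 438 nodes, peak t = 5.87 at (-41, 41, 28) mm
behavior:
  handedness: t(21) = 0.98, p = 0.34, d = 0.41
  ...
```

Reading: the boosted (AP) group shows the expected stronger 40–80 ms GFP
(0.69 vs 0.47 µV, p = 0.002); the microstate back-fitting finds one early
template whose GEV is significantly higher in the AP group (H = 5.77,
p = 0.016); and the source SPM yields exactly one suprathreshold cluster,
stronger in the AP group and lateralized to the planted left hemisphere
(its |t|-weighted centroid has x < 0). The ~9 % epoch rejection rate
reflects the injected high-amplitude frontal artifacts caught by the
±100 µV rule.

A thin command-line wrapper with `simulate`, `preprocess`, `gfp`,
`microstates`, `sources`, `behavior` and `report` subcommands is installed
at `system.file("scripts/erpmicro", package = "erpmicro")`.

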