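---
title: "erpmicro: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{erpmicro: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `erpmicro`: the statistical and
biophysical models, what their parameters mean and why the defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design decisions taken where more than one defensible
choice existed.

## The analysis problem

The package implements the electrical-neuroimaging chain used to compare
two groups of subjects on event-related potentials (ERPs) recorded from a
64-channel scalp montage: sensor-space cleaning and averaging; a
reference-free measure of response strength (Global Field Power, GFP);
topographic microstate analysis, which decomposes the ERP into a sequence
of quasi-stable scalp map configurations and quantifies each map's
presence in every subject; and distributed source imaging, which estimates
intracranial current density from the scalp fields under a spherical
conductor model and tests group differences node by node with a
cluster-extent correction for multiple comparisons. A closed-form
behavioral module (d-prime, exact binomial classification, summary t and
chi-squared tests) completes the study-level statistics.

Because raw recordings of the motivating study design are not publicly
available, the package carries a first-class simulator that generates a
complete two-group, three-condition study with a known planted effect.
Every downstream claim the test suite makes is made against that known
ground truth.

## Time and units

Latencies are milliseconds relative to stimulus onset; a window stated in
ms is a closed interval mapped to sample indices by rounding to the
nearest sample (`ms_to_index()`). Epochs span −200 to +1000 ms by default:
the baseline window runs to onset and the analysis window of interest ends
at 1000 ms. Sensor data are microvolts throughout; head geometry is in
meters; dipole moments are nanoampere-meters; source magnitudes are
reported in nominal µA/mm³ (the linear estimate of µV data without
per-subject conductivity calibration).

## Preprocessing

* **Band-pass 0.25–30 Hz**, zero phase. The filter order is 4 per
  direction (the order is not dictated by the analysis; 4 is the common
  Butterworth default, configurable). The band-pass is applied as a
  low-pass/high-pass *cascade*: a single polynomial band-pass spanning
  three decades at a 1024 Hz rate has poles so close to the unit circle
  that double-precision filtering visibly distorts the passband (a few
  percent gain error in our measurements), while the cascaded sections
  stay well conditioned. Edge transients are suppressed by odd-reflection
  padding of at least three time constants of the 0.25 Hz corner, capped
  at the epoch length.
* **Notch 50 Hz**: a constant-Q biquad (Q = 30), also zero phase. Q = 30
  makes the notch deep at 50 Hz while 45/55 Hz neighbors keep well over
  half their amplitude after the forward–backward pass.
* **Decimation to 256 Hz** by integer subsampling, phased so the
  stimulus-onset sample is kept; valid because the 30 Hz low-pass has
  already removed content above the new Nyquist frequency.
* **Artifact rejection** drops an epoch iff any channel sample exceeds
  +100 µV or falls below −100 µV, with *strict* inequalities (a sample at
  exactly ±100 µV is kept), matching the usual phrasing "above / under".
* **Baseline correction** subtracts the per-channel mean over −200–0 ms;
  **average reference** subtracts the instantaneous channel mean (an
  idempotent projection that leaves GFP unchanged).
* **Spherical-spline interpolation** of declared bad channels uses the
  standard thin-plate spline on the sphere with order m = 4, the Legendre
  series truncated at degree 50, and ridge regularization 1e−5 on the
  spline system; the package refuses to interpolate a quarter or more of
  the montage. Bad channels are declared, not auto-detected.

One approximation is worth stating: filtering is applied per epoch (with
reflection padding), whereas a continuous recording would be filtered
before epoching. With the epochs available as the unit of data, the
continuous operation cannot be reproduced exactly; the padding keeps the
difference to edge effects.

## Global Field Power

GFP(t) is the spatial standard deviation of the scalp map with the
population (1/C) normalization — the classical definition, configurable in
spirit but deliberately not parameterized, because every downstream
quantity (GEV weights, window means) assumes it. Condition collapsing is
the epoch-count-weighted mean of condition ERPs, which equals re-averaging
all epochs in one pass. The group statistic on the 40–80 ms window mean is
a pooled-variance Student t (not Welch), two-sided, with Cohen's
d = |Δmean|/pooled SD; the pooled form is what reproduces the reference
biographical statistics from printed summaries in the test suite.

## Microstates

**Segmentation** runs on the concatenated grand averages of both groups
(conditions collapsed), all maps average-referenced. The modified k-means
assigns each sample to the template maximizing *squared* spatial
correlation — so assignment ignores polarity — and re-estimates each
template as the first principal component of its assigned maps, which is
the orientation-robust generalization of the cluster mean. Template signs
are then oriented to correlate positively with the mean assigned map (a
deterministic tie-break that makes runs comparable). Empty clusters are
re-seeded at the worst-fitted sample. The best of 100 random restarts by
total GEV is kept; the restart seed is exposed.

**GEV** weights each sample's squared spatial correlation by its squared
GFP: `GEV = Σ_t (GFP_t · r_t)² / Σ_t GFP_t²`, so high-field moments
dominate, and per-template GEVs sum to the labeling's total GEV exactly.

**Model order.** Two criteria are combined:

* the cross-validation index `CV(q) = σ̂_q² ((C−1)/(C−1−q))²`, where σ̂_q²
  is the mean residual variance per degree of freedom, and
* a Krzanowski–Lai-style elbow statistic on the within-cluster dispersion
  `W(q)` (sum of squared projection residuals):
  `DIFF(q) = (q−1)^{2/C} W(q−1) − q^{2/C} W(q)` and
  `KL(q) = DIFF(q) − DIFF(q+1)`, evaluated only where the dispersion curve
  is locally convex (`DIFF(q) > 0`) — the "modified" restriction that
  suppresses spurious peaks on concave stretches.

The chosen q maximizes KL among candidates whose CV is within 5 % of the
CV minimum; ties go to the smaller q. The exact KL variant used by legacy
microstate software is not published, so this operational definition is
the package's own, validated on planted-map data where the true q is
known; structureless (white-noise) input produces no usable KL peak and
the selection falls back to the CV minimum, saying so in its `reason`
field. Perfect-fit data (zero dispersion everywhere) short-circuit to the
smallest candidate.

**Post-processing**: template pairs sharing over 92 % of variance
(squared spatial correlation > 0.92) are merged — the merged template is
the first principal component of the pooled assigned maps — and segments
shorter than 20 ms are dissolved sample-by-sample from their edges into
whichever neighboring segment's template correlates better, until no short
segment remains (alternating single-sample labelings provably collapse to
one segment).

**Back-fitting** labels each window sample of an individual ERP with the
best-correlating template (winner-take-all, no temporal smoothing, no
GFP floor — all samples participate; a configurable floor was considered
and left off because the reference procedure gives no indication of one).
Duration is the labeled-sample count times the sample period; GEV% is the
template's share of the subject's GFP-weighted topographic variance.
Group comparisons of Duration and GEV use the Kruskal–Wallis rank test
(tie-corrected H, χ²(1) p), the appropriate choice given that duration
distributions are bounded and typically non-normal; Cohen's d from group
means and SDs is reported alongside as a familiar effect-size scale.

## Head model, lead field and inverse

The conductor is three concentric spheres — brain, skull, scalp — with
relative radii 0.087 / 0.092 / 0.100 and conductivities
0.33 / 0.0042 / 0.33 S/m, the conventional three-shell values (the source
analysis that motivated this package used a sphere fitted to a template
head; without that template the spherical geometry is used directly, and
all values are configurable). Electrode directions come from an
*idealized* 10-10 construction for the 64-channel BioSemi label set:
sagittal rows at 18° steps along the nasion–inion arc, lateral slots by
rotating the midline point about the front–back axis in 18° steps. These
are not digitized positions, which matches the study design this package
mirrors (no individual electrode digitization).

The **lead field** solves the concentric-sphere boundary-value problem per
spherical-harmonic degree n: in each shell the potential is
`A_j x^n + B_j x^−(n+1)`; continuity of potential and radial current at
the two interfaces plus the insulating outer surface give a 5×5 linear
system whose solution yields the radial transfer coefficient T_n mapping
the dipole's primary expansion onto the scalp surface. The system is
row/column-equilibrated before solving because `x^n` and `x^−(n+1)` terms
span many orders of magnitude at large n. The series is truncated when
terms fall below a relative tolerance of 1e−10 (default cap n = 300); a
non-convergent node — only possible essentially on the brain shell —
raises an error naming the node. Correctness is pinned by two independent
anchors in the test suite: with equal conductivities T_n reduces to the
single-sphere closed form (2n+1)/n to machine precision, and the primary
expansion itself is checked against the free-space dipole potential
`m·(r−r₀)/(4πσ|r−r₀|³)`. Rotation invariance, linearity, average-reference
column sums and monotone depth decay complete the validation. The average
reference is applied to every column.

The **solution grid** is a cubic lattice clipped strictly inside the brain
shell; given a target count (3005 by default, ~1000 in the reduced test
configurations) the spacing is solved by bisection on the monotone
count-vs-spacing step function. Adjacency connects nodes within 10 mm, the
conventional connection radius — widened to the lattice spacing on grids
coarser than 10 mm, because otherwise a reduced grid would have no edges
at all and cluster analysis would silently degenerate to singletons.

The **inverse** is the depth-weighted minimum norm
`J = W⁻¹Lᵀ(LW⁻¹Lᵀ + λI)⁻¹u` with `W = diag(‖l_node‖^{2γ})` replicated over
the three free orientations per node (γ = 1 by default; γ = 0 recovers the
unweighted minimum norm). λ defaults to `trace(LW⁻¹Lᵀ)/(C·SNR²)` with an
assumed amplitude SNR of 3. Node activity is the Euclidean norm over the
three orientations, averaged over the analysis window.

One design decision deserves its own paragraph. The *peak* of the WMN
magnitude is a poor localizer: across the full range of depth-weight
exponents and regularization strengths we evaluated, noiseless
single-dipole peaks land several grid spacings away (minimum-norm
solutions are biased superficial, and on a head with electrodes only on
the upper hemisphere the depth weight additionally inflates the
electrode-free bottom of the sphere). This is consistent with the
minimum-norm literature and with the centimeter-level precision commonly
attributed to such inverses. The package therefore also provides the
standard remedy as an option: the sLORETA-style variance standardization
`sqrt(J_iᵀ R_ii⁻¹ J_i)`, with `R_ii` the node's 3×3 resolution block,
available via `apply_inverse(..., standardized = TRUE)`. For the
unweighted operator at small λ this standardized magnitude localizes a
noiseless single dipole exactly — the property the localization checks in
the test suite and acceptance script exercise. The default (WMN
magnitude) remains the current-density estimate used for group mapping,
where per-node standardization is irrelevant anyway: a two-sample t-test
is invariant to any per-node rescaling.

## Cluster-extent correction

Group maps are compared node-wise with pooled-variance two-sample t-tests
(positive t = first group stronger; zero-variance nodes get t = 0 and are
flagged). Multiple comparisons are handled AlphaSim-style: i.i.d. standard
normal fields on the grid are smoothed with a Gaussian kernel of given
FWHM (row-normalized weights over the irregular node set, truncated at
twice the FWHM), standardized by each node's exact post-smoothing SD,
thresholded two-sided at the node-level p, and the maximum same-sign
connected cluster size recorded; the calibrated extent is the smallest K
with `P(max ≥ K) ≤ α`. Suprathreshold clusters in the real contrast are
formed within sign (clusters never mix signs) and reported with size, peak
node and an |t|-weighted centroid — the centroid, not the peak, is the
stable location summary of an extended minimum-norm cluster, and it is
what the lateralization checks use.

Two reference thresholds coexist in the source literature this mirrors:
cluster membership at p ≤ 0.01 and a stricter p < 0.005 used for the
extent calibration; the package defaults to node_p = 0.01 everywhere and
exposes 0.005 as a plain argument, preserving the ambiguity rather than
resolving it silently.

Discreteness matters when validating the calibration: with kernels no
wider than the node spacing, the max-cluster-size distribution is strongly
discrete and the calibrated extent is conservative (true FWE well below
α — still a valid bound, and asserted as such in the unit tests). The
acceptance-level check of "empirical FWE ≈ α" therefore runs with a kernel
about twice the node spacing (30 mm on the 14 mm reduced grid), where the
tail is fine-grained enough for the attained FWE to sit near the nominal
level.

## The synthetic study

The generator emulates the study conditions end to end: two groups
(11 vs 12 subjects by default), three conditions of 90 epochs each,
1024 Hz sampling over −200–1000 ms epochs. Each subject's noise-free
signal is the forward projection of dipolar sources with
Gaussian-windowed half-sine time courses (a half-sine arch over
[latency ± width/2] tapered by a Gaussian of σ = width/4 — smooth,
band-limited, fully described by latency/width/amplitude). The default
layout is an early left temporo-parietal source (peak 60 ms, width 40 ms,
at the grid node nearest (−52, −40, +20) mm, radially oriented) and a
bilateral temporal pair peaking at 100 ms shared by both groups. The
planted group effect multiplies the early source by `ap_boost` (default
1.5 — a free simulation parameter; the true effect size of the motivating
finding is unknown). Source amplitudes were fixed once so that the
simulated NAP grand-average GFP over 40–80 ms sits near 0.5 µV, the scale
of real early auditory ERPs. Per-subject lognormal amplitude jitter
(SD 0.2) creates between-subject variability; sensor noise is i.i.d.
Gaussian at 1.5 µV SD per channel and sample; 9 % of epochs receive a
single-arch frontal deflection of 150 µV peak, emulating ocular artifacts
for the rejection rule to catch (and matching the reference study's mean
trial-rejection rate).

Randomness is organized in per-subject substreams derived from the master
seed by a fixed affine counter scheme, so any subject is reproducible in
isolation. The substream depends only on the *within-group* index: with
the effect off and the noise off, the two groups are draw-for-draw
identical — a convenient invariance for tests. The flip side is that
effect-off *group comparisons* must not reuse the same indices in both
groups; the null-calibration checks therefore simulate one pool of
subjects and split it.

What the generator does **not** emulate: realistic music-evoked ERP
morphology (component sequences, latency jitter across trials),
condition-specific effects (all three conditions share the signal and
differ only in noise, matching a design whose effect of interest is
condition-independent), spatially correlated or 1/f sensor noise (a 1/f
hook exists but is off), eye-blink waveform shape beyond
threshold-exceeding deflections, and anatomical realism (no gray-matter
restriction beyond the brain shell, no atlas). Passing tests on this
fixture therefore demonstrate that the pipeline recovers a planted
dipolar amplitude difference under Gaussian noise — not that it would
recover arbitrary effects in real recordings.

## Problem sizes in the checks

The test suite and acceptance script run a reduced configuration chosen to
exercise every stage at desk scale: 6 vs 6 subjects with 30 epochs per
condition simulated directly at 256 Hz, a ~1000-node grid (13.8 mm
spacing), 1000–4000 Monte-Carlo iterations for the extent calibration,
500 independent null replicates for the FWE check, and 200 effect-off
replicates for the rejection-rate check; the localization sweep uses 20
random interior nodes. The full-scale defaults (11 vs 12 × 90 epochs at
1024 Hz, 3005 nodes, 10 000 iterations) run the same code paths.

## Known limitations

* The spherical three-shell model and idealized montage put a
  centimeter-scale ceiling on localization realism; no BEM/FEM, MRI or
  digitized positions.
* Ocular artifact handling is threshold rejection only; the ICA step of
  typical lab pipelines is analyst-dependent and deliberately out of
  scope (an EOG-regression hook is left unimplemented).
* EDF support is a minimal importer/exporter (int16 quantization, one
  data record per epoch); BrainVision formats are not written.
* The modified KL criterion is an operational reconstruction; other
  implementations may choose a different variant and select a different q
  on borderline data.
* Cluster-extent calibration with kernels at or below the node spacing is
  conservative by discreteness (see above).
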