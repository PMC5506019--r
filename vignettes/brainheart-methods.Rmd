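---
title: "Models and methods: connectivity, heart rate and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: connectivity, heart rate and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainheart)
```

# The study design the package implements

`brainheart` implements an analysis pipeline for experiments in which brief
affective interventions (a positive "gratitude" and a negative "resentment"
script) are delivered inside the scanner while BOLD fMRI and fingertip
photoplethysmography (PPG) are recorded simultaneously. The design has five
sessions per subject — baseline rest, a first 5-minute intervention, rest,
the second intervention, rest — with the intervention order counterbalanced
across subjects (set I: gratitude first; set II: resentment first). Each
session acquires 155 volumes at TR = 2 s; the first five are discarded,
leaving 150 volumes (300 s) per session and 750 per subject. PPG is sampled
at 50 Hz during the two intervention sessions.

The scientific questions map onto five analysis products:

1. **Heart rate by condition.** PPG is converted to beats, beats to
   instantaneous heart rate (HR), and session means are compared by paired
   t-test; per-window HR is compared window by window.
2. **Seed-based connectivity.** Fisher-z correlation maps from spherical
   seeds (PCC, VMPFC, bilateral amygdala, bilateral nucleus accumbens
   analogues), contrasted between conditions under permutation cluster-level
   family-wise error (FWE) control.
3. **Inter-network connectivity.** Temporal-concatenation group ICA
   (TC-GICA: 30 subject-level principal components, concatenated, reduced
   to 20, unmixed by infomax), dual regression, template matching to five
   networks (default mode, temporolimbic, salience, left/right
   frontoparietal), and 10 network-edge Fisher-z values per session tested
   with paired t, repeated-measures ANOVA, Bonferroni post-hocs, and
   Benjamini-Hochberg FDR.
4. **Brain-heart coupling.** Sliding-window FC (60 s windows, 10 s steps,
   25 windows per session) correlated across windows with sliding-window
   HR — one synchronization coefficient per subject per edge or voxel —
   tested at the group level (one-sample t; FDR on edges, cluster FWE on
   voxels).
5. **Behaviour.** Linear regressions of connectivity on HADS
   anxiety/depression and SDT autonomy/competence/relatedness subscales.

Because no public dataset accompanies this design, the package ships a
synthetic cohort generator whose defaults *are* the study conditions, with
injectable ground-truth effects, and every stage is validated against that
generator.

# The synthetic generator

## Network signal model

A `network_atlas` partitions the voxel grid into K contiguous rectangular
parcels (each at least 27 voxels) separated by background. Each network has
a latent time course: a sum of 8 random-phase sinusoids with frequencies
drawn uniformly in the 0.009–0.08 Hz pass band, plus a small AR(1) jitter
(2% of variance, coefficient 0.5), standardized to unit variance. The
jitter keeps the latents from being exactly periodic while leaving at least
90% of spectral power inside the band (a tested invariant). Every voxel of
a network carries its latent plus white Gaussian noise (`noise_sd`, default
0.5); background voxels carry noise plus tissue-specific fluctuations; a
smooth random-walk drift can be leaked into all voxels (`motion_leak`) to
give nuisance regression something real to remove.

Latents for different networks are **independent by default**
(`base_r = 0`): every dependence recovered downstream is then attributable
to an explicitly injected effect. Injected effects enter a per-condition
target correlation matrix realized by Cholesky mixing: `fc_effects` rows
add `delta_r` to named edges in named conditions (default: +0.3 on
DMN–salience after the gratitude intervention), and `behavior_effects`
rows make an edge depend linearly on a subject's behavioural score.

## Heart rate and PPG

Session mean HR is `hr_baseline_bpm` (70) plus a subject offset
(SD 7 bpm), a per-session fluctuation (SD 4.2 bpm, so paired condition
differences have SD ≈ 6 bpm), and a −3 bpm shift for the gratitude
condition — the effect size the analysis is meant to detect. Windowed HR
fluctuates around the session mean with SD 2 bpm.

The coupling construction works on the analysis window grid. The realized
windowed FC of the designated edge (`sync_edge`, default
temporolimbic–salience) is computed from the latents; the windowed HR
target is `sync_rho` times the standardized windowed FC plus
`sqrt(1 - sync_rho^2)` times noise that has been orthogonalized against the
windowed FC, so the correlation on the grid is exactly `sync_rho`. The
noise component is generated on the 10 s bin grid and passed through the
same 60 s moving-average windowing, giving the target the temporal
smoothness that overlapping windows impose on any physical rate curve —
without this the target would demand implausibly rough beat sequences.
When `sync_rho = 0` the orthogonalization is skipped, leaving an honest
sampling null rather than an artificially exact zero.

Beat times are back-filled from the windowed target by minimum-norm
deconvolution of the overlapping-window averaging onto piecewise-constant
10 s bin rates, followed by damped fixed-point corrections against the
realized windowed means (computed exactly as the analysis computes them),
with bin rates confined to ±20 bpm around the session mean. The stored
per-window truth is the *realized* windowed mean of the generated beats,
which the analysis recovers to within 0.5 bpm. The PPG waveform is one
Gaussian pulse (100 ms FWHM) per beat on a 50 Hz grid plus optional noise.

Behavioural scores follow the instrument ranges: HADS subscales are
integers clipped to 0–21 (mean 6 and 5, SD 3); SDT subscales are continuous
(mean 5, SD 1).

## What the generator does not emulate

No hemodynamic response function, no scanner artifacts or spatial noise
correlations, no respiration, no head motion geometry (only confound
*time series*), no anatomical variability — the parcels are axis-aligned
blocks on a common grid, standing in for spatially normalized data. Passing
tests therefore demonstrate that the *algorithms* recover known structure
under the study's sampling design, not that the pipeline is robust to every
artifact of real scanner data.

# Analysis choices

**Preprocessing order** is fixed: trim 5 volumes → optional 6 mm Gaussian
smooth → OLS nuisance regression (6 motion parameters + white-matter and
CSF means + intercept) → zero-phase band-pass. Regressing before filtering
follows the conventional listing of these steps; the residuals are exactly
orthogonal to the confounds, and the band-pass (forward–backward order-2
Butterworth, 0.009–0.08 Hz) then removes drift. Series are demeaned and
reflect-padded (50 samples) before `filtfilt` to suppress edge transients
at 150 samples, and the output is demeaned again because the pass band
excludes DC — over only ~3 cycles of the slowest in-band component a
finite-series mean would otherwise survive. Pass-band amplitude is
preserved within 5% at 0.04 Hz and stop-band amplitude at 0.2 Hz is
attenuated below 10% (tested by least-squares sinusoid fits).

**Window grid.** `n_windows = floor((duration - window)/step) + 1`, first
window at the start of the *retained* series; with trimming, the grid's
absolute clock starts at 10 s, and windowed HR uses the same absolute
times via the PPG time stamp, so brain and heart windows align. Windowed
FC uses the 30 in-window volumes; windowed HR averages instantaneous HR at
interval midpoints, flagging windows with fewer than 10 beats and leaving
empty windows missing rather than zero. Missing windows are dropped
pairwise in the synchronization correlation; fewer than 3 complete pairs,
or zero-variance HR, yields a flagged missing value.

**Peak detection** (unspecified in the source design) is local-maxima
detection with a 300 ms refractory distance and a prominence threshold of
0.3 of the trace amplitude range — transparent, testable, and invariant to
amplitude rescaling. Peak times are refined by quadratic interpolation
through the peak and its two neighbours: the 50 Hz grid alone quantizes
inter-beat intervals to 20 ms (more than 1 bpm at resting rates), while
the refined times recover generator heart rate to well under 0.1 bpm.
Intervals outside (250, 2000) ms are flagged as artifacts and excluded
rather than interpolated — note this means a single dropped beat is only
flagged when the doubled interval exceeds 2 s; the per-window HR statistic
is the mean of instantaneous HR in the window.

**Infomax ICA.** Natural-gradient infomax with the hyperbolic-tangent
score `phi(u) = tanh(u)` for super-Gaussian sources, switching to
`u - tanh(u)` for sources whose running excess-kurtosis estimate falls
below −0.5 (the extended sub/super switch; the conservative threshold
keeps transient mixtures — which can look mildly sub-Gaussian — on the
super-Gaussian score). Initial learning rate 0.3, annealed by 0.9 whenever
the update direction swings by more than 60° and by 0.99 per iteration
after 512 iterations; convergence when the weight-update Frobenius norm
falls below 1e-6. Because infomax has local optima (on block-structured
spatial sources a basin in which two networks stay pairwise mixed exists),
the unmixing is run from 4 seeded random orthogonal initializations and
the solution with the highest infomax objective — `log|det W|` plus the
mean source log-density under each source's sub/super model — is kept; the
restart seeds derive from the one user seed, so decompositions remain
deterministic. Scale and sign indeterminacies are
fixed by reporting unit-variance sources with non-negative skewness.
All-Gaussian inputs are flagged (`low_kurtosis`) with a warning since they
are not identifiable. On the 8-subject default cohort the matched group
components correlate with the ground-truth parcels above 0.99.

**Dual regression** uses variance-normalized spatial maps in the stage-1
design; stage-2 time courses are not re-normalized. Template matching
maximizes total absolute spatial correlation over injective assignments
(exact branch-and-bound; trivial at 5×20) with a floor of 0.2 per network,
below which an explicit unmatched-network error is raised; the match
records the correlation sign so anti-correlated components can be flipped.

**Statistics.** t tests, the one-way within-subject ANOVA
(`F = MS_cond / MS_err`, df `(C-1, (C-1)(n-1))`, no sphericity correction
by default with Greenhouse–Geisser as an option), and slope tests are
closed-form and vectorized over targets; all are cross-checked against
independent sum-of-squares oracles and against `t.test`/`aov` in the test
suite. Zero-variance targets yield flagged missing values, not numbers.
BH-FDR wraps `stats::p.adjust` and is tested against a hand-enumerated
step-up rule. Where a group summary of per-subject correlations is tested
(synchronization), the correlations are Fisher-z transformed first.

**Cluster-level FWE** replaces parametric random-field corrections with
permutation max-cluster-size inference: voxelwise statistic maps are
thresholded at the cluster-defining threshold (two-sided uncorrected
p = 0.001 for FC contrasts, 0.005 for synchronization and behavioural
regressions), positive and negative suprathreshold sets are labelled
separately under an 18-neighbour lattice rule (6/26 configurable), and
observed sizes are referred to the permutation null of the maximum cluster
size with `p_fwe = (1 + #{null >= size}) / (n_perm + 1)` — never below the
floor `1/(n_perm+1)`. Permutation schemes follow the design's
exchangeability: sign flips for one-sample maps, within-subject condition
swaps (equivalently sign flips of paired differences) for paired designs,
and score shuffling for regressions. Empirical FWE on pure-noise maps is
verified to stay at or below nominal within Monte-Carlo error.

**Degenerate inputs.** Constant seeds, empty masks and ROIs, rank-deficient
confound or map designs, mismatched grids, sessions shorter than one
window, capacity-violating atlas requests, and non-physiological windows
all raise classed errors (`brainheart_config_error`, `_data_error`,
`_capacity_error`, `_insufficient_signal`, `_non_convergence`,
`_unmatched_network`) rather than propagating silent numbers. Correlations
are clipped to `±(1 - 1e-7)` before `atanh`, so perfect correlations map to
a finite ceiling.

# Problem sizes used in tests

The test and acceptance workloads were chosen as the smallest sizes at
which each property is meaningfully testable: a 16×16×8 grid
(2048 voxels, 5 parcels of 256) for the ICA recovery cohort of 8 subjects;
a 16×8×2 grid (256 voxels) for Monte-Carlo work — 20 replicate cohorts of
29 subjects for coupling recovery and its null, 50 replicates of 29 paired
sessions for heart-rate power, 20 pure-noise replicates of 12 subjects on
a 12×12×6 grid with 199 permutations for FWE calibration. Statistical
oracle checks use ≤ 10-subject tables where the brute-force sums are
transparent. The pipeline orchestrator (`run_pipeline()`) defaults to the
8-subject smoke configuration with 99 permutations.

# Interpreting recovered coupling strength

The generator makes the windowed-FC/HR correlation exact on the window
grid *for the latent series*. The analysis estimates windowed FC from
preprocessed voxel data, so the recovered per-subject synchronization is
mildly attenuated (band-pass edge effects and nuisance regression perturb
the 30-volume windowed correlations): at an injected `sync_rho = 0.6` the
estimated per-subject values centre near 0.5, and the acceptance band
(0.6 ± 0.15) reflects that attenuation rather than estimation bias of the
statistic itself — `fc_hr_sync` on the latent truth recovers `sync_rho`
to within beat-quantization error.

# Known limitations

- The atlas's rectangular parcels make template matching easier than on
  real anatomy; matching robustness to overlapping or distorted networks is
  untested.
- The beat back-fill quantizes HR at the 10 s bin scale; heart-rate
  variability on faster time scales (and hence HRV metrics) is not
  emulated.
- The permutation schemes assume exchangeability (no autocorrelated
  between-subject structure), as do the parametric tests they complement.
- With `n_perm` permutations the smallest attainable `p_fwe` is
  `1/(n_perm+1)`; the 99-permutation smoke default resolves only to 0.01.
- Group ICA at 20 components on 5-network data leaves 15 components of
  structured residual; template matching handles this, but component
  *counts* are not interpretable as network counts.
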