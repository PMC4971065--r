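---
title: "EEG microstate analysis and temporal sorting of resting-state networks"
author: "EEGmicrostates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis and temporal sorting of resting-state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EEGmicrostates)
```

# The model

Resting-state EEG does not meander continuously through scalp
configurations: the electric field topography stays quasi-stable for tens
of milliseconds and then switches abruptly. These quasi-stable epochs --
*microstates* -- are conventionally reduced to four topography classes
labeled A-D, and their temporal statistics (how long each class lasts, how
often it occurs, how much of the recording and of the topographic variance
it covers, and how classes transition into one another) discriminate
clinical populations. This package implements the full analysis chain:

1. **GFP peak extraction** (`computeGFP()`, `findGFPPeaks()`,
   `extractTopographies()`). Global field power is the population standard
   deviation across channels of the average-referenced topography at one
   sample. Local GFP maxima are the moments of highest topographic
   signal-to-noise; their maps are the clustering input.
2. **Polarity-invariant modified K-means** (`modifiedKMeans()`). Peaks
   from all subjects of both groups are concatenated and clustered by
   absolute spatial correlation: a map and its sign-flip belong to the
   same class. The objective is the GFP-weighted global explained
   variance
   $GEV = \sum_p (GFP_p\,\rho_p)^2 / \sum_p GFP_p^2$,
   where $\rho_p$ is the spatial correlation between peak map $p$ and its
   assigned template.
3. **Choice of K** (`selectK()`): the predictive residual-variance
   criterion $CV(K) = \hat\sigma^2\,((C-1)/(C-1-K))^2$ with $C$ channels,
   minimized over a candidate range; $\hat\sigma^2$ is the mean per-peak
   residual variance after projecting each map on its assigned template.
4. **Canonical labeling** (`canonicalLabeling()`): the fitted templates
   are matched one-to-one against geometry-derived idealizations of the
   A-D classes (`canonicalTemplates()`), maximizing total $|\rho|$ over
   all permutations.
5. **Backfitting and temporal parameters** (`backfit()`,
   `computeMetrics()`): every sample of the continuous recording is
   assigned to the template with the highest $|\rho|$; run-length
   statistics yield mean duration (ms), occurrence (1/s), ratio of total
   time, per-state GEV, and the sample-to-sample transition matrix.
6. **Group comparison** (`rmAnova()`, `posthocResidualT()`): the group
   $\times$ state interaction is tested multivariately on the $K-1$
   within-subject difference contrasts with age and gender as covariates
   (Wilks' Lambda, Rao's F), followed by per-state pooled-variance t-tests
   on age/gender-adjusted residuals with a Bonferroni threshold of
   $0.05/K$.
7. **Temporal sorting of RSNs** (`buildRegressors()`, `sortComponents()`,
   `aggregateZ()`): each state's occupancy is expressed as a boxcar on a
   100 Hz grid, convolved with the canonical double-gamma HRF, sampled at
   the volume times, and used (jointly with the other states, plus an
   intercept) in an OLS regression of each RSN component time course.
   Per-subject slopes are averaged per group and standardized across the
   components within each (state, group) cell; pairings with $Z \ge 1$
   are flagged.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `band` in `preprocess()` | 1-40 | Hz | analysis band; the upper edge keeps alpha and beta, drops line noise |
| `targetFs` | 125 | Hz | analysis rate after decimation |
| `exclusionZ` in `findGFPPeaks()` | 5 | robust Z | amplitude-outlier rule replacing visual rejection of artifact peaks |
| `K` | 4 | classes | the conventional resting-state template count |
| `nRestarts`, `tol`, `maxIter` | 50, 1e-6, 100 | -- | restart budget and the "GEV stable" convergence rule |
| `templateUpdate` | `"mean"` | -- | polarity-aligned averaging; `"eigen"` uses the dominant eigenvector |
| `gfpFloorFrac` in `backfit()` | 0.5 | fraction of median GFP | samples below the floor inherit the previous label |
| HRF (`canonicalHRF()`) | peak 6 s, undershoot 16 s, ratio 6, length 32 s | s | canonical double-gamma |
| `gridHz` in `buildRegressors()` | 100 | Hz | fine grid so ~100 ms runs are not aliased by TR binning |

## Why the backfit GFP floor is 0.5

The default backfit floor deserves its own paragraph because it is the one
place where this implementation departs from the naive per-sample argmax.
At amplitude troughs of the alpha-band carrier the topography is dominated
by sensor noise: its correlation with *every* template is small and
essentially random, so an unconditional argmax shatters genuine 100 ms
runs into fragments and biases mean durations far downward (we measured
roughly -35% at the generator's SNR of 3). A sample whose GFP is below
half the median GFP carries no usable topographic information -- at SNR 3
the noise-only GFP sits near one third of the median -- so such samples
inherit the previous label, which is exactly the quasi-stability
assumption the segmentation encodes. With the floor at 0.5 the recovered
cohort-mean durations land within a few percent of the generating values
while per-sample agreement with the ground truth *increases*. For
noise-free data the floor is irrelevant (any small value gives identical
labels), and it is exposed as a parameter for users who prefer the
unconditional assignment.

## Template update: averaging vs eigenvector

The default update averages the polarity-aligned assigned maps -- the
procedure described in the microstate literature this pipeline follows.
That update is a heuristic: it does not maximize any global objective, and
its fixed points can sit slightly below the best attainable GEV. The
`"eigen"` variant uses the dominant eigenvector of the GFP-weighted outer
product of the assigned maps, which is exactly the GEV-optimal template
for a fixed assignment; the resulting iteration is monotone in GEV, and on
small instances (where exhaustive enumeration over all polarity-invariant
assignments is feasible) it attains the global optimum with 50 restarts in
every instance we generate. The test suite asserts optimality for the
eigen variant and only boundedness for the averaging default; in practice
the two agree to three decimals in GEV on realistic data.

# What the generator emulates -- and what it does not

`simConfig()` / `simulateCohort()` produce a two-group cohort matched to
the emulated study conditions: 64-channel extended 10-20 EEG at 125 Hz,
600 s per subject, 16 subjects per group, four ground-truth template maps,
and 15 RSN component time courses at TR 2.2 s over 270 volumes.

* **Dwell times** are gamma-distributed (shape 2) with per-group,
  per-state means defaulting to the published patient/control values
  (A 87.58/101.44, B 90.47/80.02, C 75.92/72.92, D 61.14/61.54 ms). The
  gamma choice produces unimodal ~100 ms runs with exactly configurable
  means; the true dwell distribution of real data is unknown, so the
  shape is a config field.
* **The amplitude carrier** is a rectified 10 Hz sinusoid with slow phase
  drift, so GFP peaks arrive at alpha half-cycles -- mirroring the fact
  that microstate segmentation rides mainly on alpha-band activity.
* **Noise** is spatially white Gaussian, scaled so state-signal RMS over
  noise RMS equals `snr` (default 3). Real EEG noise is spatially
  correlated; white noise keeps the SNR interpretable and is the one
  place where passing tests say the least about real recordings.
* **RSN coupling**: each component time course is the coupling-weighted
  sum of HRF-convolved state regressors plus AR(1) noise
  (coefficient 0.3). The default coupling matrix drives component 2 and
  10 from state A, 7 from B, 4 and 9 from C, and 6 from D -- a pattern of
  the same shape as the published microstate-RSN pairings.
* **Next-state kernel** is uniform over the other $K-1$ states by
  default; a full transition matrix can be configured for
  transition-recovery experiments.

Not emulated: MR gradient and cardioballistic artifacts, ocular/muscle
artifacts, sleep-stage dynamics, spatially correlated sensor noise, and
volumetric fMRI data (component time courses are generated directly).
Consequently, passing the simulation-based checks demonstrates the
correctness and calibration of the *algorithms*, not robustness to the
artifact structure of real simultaneous EEG-fMRI.

# Numerical and design choices

* **Population (divide-by-C) SD** for GFP -- the conventional definition.
* **Zero-phase filtering** (forward-backward Butterworth; 2nd-order
  high-pass, 8th-order low-pass) so GFP peak latencies are not shifted;
  the steep low-pass keeps 50 Hz leakage under 5% after decimation.
* **Plateau peaks** take the first sample of the plateau; recording
  endpoints are never peaks.
* **Peak exclusion** replaces the visual rejection of artifact-laden
  peaks by a deterministic rule: peak GFP above median + 5 MAD of the
  peak amplitudes. Any fixed rule is a surrogate; 5 robust SDs only
  removes gross outliers.
* **Ties** in competitive assignment go to the lowest template index;
  empty clusters are re-seeded from the worst-fit peak; a template update
  whose aligned sum cancels exactly keeps the previous template.
* **Convergence** is a relative GEV change below 1e-6 (cap 100
  iterations, 50 restarts) -- a quantified version of "until the GEV
  becomes stable".
* **Transition matrices** are sample-to-sample including the diagonal
  (staying counts as a transition to self); a run-level, self-excluded
  matrix is also computed for comparability with literature that reports
  run-wise transitions.
* **Edge runs** are included in duration averages (`trimEdges = FALSE`);
  the exact duration-occurrence-coverage identity is asserted on
  edge-trimmed sequences.
* **Wilks' Lambda** is computed on difference contrasts with the group
  term entered after the covariates, converted to F by Rao's
  approximation (exact for a single-df hypothesis). For transition
  probabilities the off-diagonal row-normalized entries replace the
  per-state vector. Degenerate designs (e.g. constant covariates
  producing a singular fit) are reported as degenerate results rather
  than errors.
* **Post hoc t values** use pooled-variance two-sample t-tests on
  residuals from the pooled age+gender regression; published analyses of
  this design report far larger t magnitudes than any two-sample
  convention can produce for 32 subjects, and the convention that
  produced them is not recoverable, so this package documents its own.
* **Z-score population**: slopes are standardized across the 15
  components within each (microstate, group) cell -- the reading under
  which "Z of at least one" is a per-heat-map-row criterion. Only
  positive flags are interpreted; negative couplings are reported but not
  flagged. Standardizing across microstates instead is a one-line change
  on the group-mean matrix and is deliberately not a supported option
  until real data motivates it.
* **TANOVA** aligns polarity before computing global map dissimilarity
  and enumerates all group splits exactly whenever they fit the
  permutation budget; permuted splits whose polarity-opposed maps cancel
  to a zero-GFP mean count conservatively as hits.
* **EDF I/O** is implemented directly (256-byte header, 16-bit
  little-endian records); round trips are exact to the 16-bit
  quantization step of each channel's range.

# Problem sizes used by the test suite

The automated checks run on scaled cohorts chosen so the full suite
completes comfortably on a single CPU while keeping every rate assertion
well-powered: template recovery uses one 4-subject cohort at the full
600 s; K-selection is checked over 20 single-subject 120 s recordings;
dwell-time recovery and the group sign pattern over twenty 16-subject
cohorts of 150 s each; statistical calibration over 200 null cohorts
(8 per group) and 40 effect cohorts (16 per group) simulated at the
label-sequence level; sorting recovery over twenty 12-subject cohorts at
the full 270-volume scan length. `scripts/acceptance.R` re-runs the same
computations at slightly smaller counts and writes the resulting
quantities as JSON.

# Known limitations

* The averaging template update is order-free but objective-free; its GEV
  can sit marginally below the eigenvector optimum.
* The cross-validation criterion assumes white residuals across channels;
  heavily rank-deficient montages (after aggressive interpolation) would
  bias $\hat\sigma^2$.
* The amplitude-outlier peak exclusion models only one artifact mode
  (high-amplitude transients); low-amplitude structured artifacts pass
  through.
* Group statistics assume one recording per subject; repeated sessions
  would need a mixed-model extension.
* The CLI reads whole recordings into memory; ~10 min of 64-channel data
  at 125 Hz is a few tens of MB, so this is comfortable for the intended
  scale but not for high-density clinical archives.

# A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- simConfig(durationS = 150, nSubjectsPerGroup = 8)
sim <- simulateCohort(cfg, seed = 1)
pip <- microstatePipeline(sim$recordings, sim$subjects,
                          K = 4, nRestarts = 20, seed = 1)
pip$clustering
rmAnova(pip$metricsTable, sim$subjects, "mean_duration")
```
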