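# EEGmicrostates

Resting-state EEG **microstate** analysis, and temporal coupling of the
resulting microstate sequences to fMRI **resting-state network (RSN)**
time courses — the analysis chain used to compare brain-state dynamics
between a patient group and matched controls (e.g. adolescents with
narcolepsy vs. healthy adolescents), implemented as a tested, reusable R
package with a seeded synthetic-data generator so that every stage can be
validated against known ground truth.

## Who this is for

EEG/fMRI researchers who want a transparent, scriptable implementation of
the standard microstate pipeline — GFP peak extraction, polarity-invariant
modified K-means, backfitting, temporal parameters, group statistics, and
HRF-based temporal sorting — without depending on GUI tools, plus
methodologists who want a generative model with known ground truth to
probe how those algorithms behave.

## The method in brief

- **GFP**: at each sample, the population standard deviation across the
  average-referenced channels; local GFP maxima carry the cleanest
  topographies.
- **Clustering**: peak maps from all subjects (both groups pooled) are
  clustered by absolute spatial correlation ρ (a map and its polarity
  flip are the same state). The objective is the GFP-weighted global
  explained variance, GEV = Σₚ(GFPₚ ρₚ)² / Σₚ GFPₚ²; the number of
  classes K is chosen by the predictive residual-variance criterion
  CV(K) = σ̂²·((C−1)/(C−1−K))², and templates are given canonical A–D
  labels by best-permutation matching.
- **Backfitting**: every sample of the continuous EEG is assigned to the
  template with the highest |ρ|, giving per state the mean duration (ms),
  occurrence (1/s), ratio of total time, GEV, and the row-stochastic
  transition matrix.
- **Group comparison**: a repeated-measures multivariate test of the
  group × microstate interaction (Wilks' Λ with Rao's F) with age and
  gender covariates, and per-state post hoc t-tests on covariate-adjusted
  residuals at the Bonferroni threshold 0.05/K.
- **Temporal sorting**: state occupancies are convolved with the
  canonical double-gamma HRF, sampled at the fMRI TR, and regressed
  jointly against each RSN component time course; group-mean slopes are
  standardized to Z across components, flagging pairings with Z ≥ 1.

Details, defaults, and design rationale are in the methods vignette
(`vignettes/microstate-analysis.Rmd`).

## Worked example

```r
library(EEGmicrostates)

cfg <- simConfig(durationS = 150, nSubjectsPerGroup = 8)   # scaled cohort
sim <- simulateCohort(cfg, seed = 1)
pip <- microstatePipeline(sim$recordings, sim$subjects,
                          K = 4, nRestarts = 20, seed = 1)
pip$clustering
#> ClusteringResult: K=4, GEV=0.9480, CV=6.2688, 48000 peaks, 3 iterations (converged)

rmAnova(pip$metricsTable, sim$subjects, "mean_duration")
#> GroupStatsResult [mean_duration]: Wilks' Lambda = 0.0314, F(3, 10) = 102.758, p = 8.179e-08
#>  state          t            p mean_control mean_patient
#>      A  8.4375770 7.328047e-07    103.86754     89.63235
#>      B -7.2061848 4.521163e-06     80.81660     90.72537
#>      C -2.3898333 3.147561e-02     74.97074     78.61830
#>      D  0.0112699 9.911671e-01     61.89472     61.39378
```

Reading the output: the four fitted templates explain 94.8% of the
GFP-weighted topographic variance of the 48 000 pooled peak maps. The
group × microstate interaction on mean duration is strongly significant,
and the post hoc t-tests recover the generating pattern — controls dwell
longer in microstate A (103.9 vs 89.6 ms), patients dwell longer in B
(90.7 vs 80.8 ms) and C, and D does not differ — i.e. the pipeline
recovers the two-group dwell-time structure the generator planted (its
defaults are the published patient/control Table values).

A file-based workflow (EDF or TSV recordings in, TSV tables out) is
available through the thin CLI at `inst/scripts/microstate_cli.R` with
subcommands `simulate`, `segment`, `metrics`, `stats`, and `sort-rsn`,
each taking `--config` (YAML), `--seed`, and `--out`.

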