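# canalrepro

Reproducibility analysis of repeated mandibular-canal localisations.

When an automated system marks the mandibular canal — the channel carrying
the inferior alveolar nerve from the mandibular foramen to the mental
foramen — as a 3D centerline in cone beam CT, the clinically important
question for longitudinal use is *test–retest stability*: if the same
patient is scanned again, how much does the system's agreement with an
expert change? `canalrepro` implements the statistical machinery for that
question, for researchers evaluating automated canal localisation (or any
tubular-structure centerline method) on repeated-scan cohorts.

## What it computes

**Geometric agreement per canal and scan**

* *SMCD* — symmetric mean curve distance between two centerlines: both
  curves resampled at uniform arc length (0.5 mm), mean exact
  point-to-polyline distance taken in both directions and averaged.
* *DSC* and *ASSD* — Dice overlap `2|A∩B|/(|A|+|B|)` and average symmetric
  surface distance between 1.5 mm diameter tube masks voxelized from the
  centerlines (surface = foreground voxels with a six-connected background
  neighbour; distances in mm between surface voxel centres).

**Within-subject repeatability of SMCD** (canals as independent subjects,
never pooled across sides), for unbalanced designs with `K_i` repeated
scans per canal:

    WMS = Σ_i Σ_k (Y_ik − Ȳ_i)² / (n (K − 1)),
    K   = (N − ΣK_i²/N) / (n − 1),
    wSD = √WMS,   RC = 1.96 √2 wSD ≈ 2.77 wSD

`RC` bounds the difference between two repeated measurements of the same
canal with 95% confidence; `K` is a downward-corrected effective replicate
count that collapses to `k` for balanced designs.

**A Bayesian repeatability measure for ordinal quality ratings.** Experts
rate each segmentation on a 0–4 Likert scale (3–4 = diagnostically fully
usable). Rater behaviour is modelled with a partial credit model with
subject random effects, `p(y = h | x, α_j, δ_j) ∝ exp(Σ_{m<h} α_j (x −
δ_{jm}))`, fitted by MCMC (JAGS), and summarised by the repeatability
measure

    RM_j = (1/n) Σ_i Σ_h p_j(y_i = h | x_i, α_j, δ_j)²,

the probability that two independent ratings of the same segmentation
coincide — reported as a posterior mean with 95% credibility interval per
rater and for the across-rater average, on the ordinal and on the
binarized diagnostic-suitability scale. Descriptive score summaries,
error-type majority voting and intra-/inter-observer accuracies round out
the qualitative report.

**A synthetic cohort generator** with known ground truth (repeated-scan
structure, smooth within-subject centerline perturbation with a calibrated
SMCD scale, canal truncation and dropout, PCM-generated ratings), because
the clinical datasets this analysis targets are access-restricted. Every
estimator in the package is tested by recovering the generator's
parameters.

## Worked example

```r
library(canalrepro)

cfg <- cohort_config(n_patients = 20, seed = 7)
cohort <- simulate_cohort(cfg)
records <- run_metrics(cohort$curves_radiologist, cohort$curves_dls,
                       manifest = cohort$manifest, masks = FALSE)
repeatability(group_measurements(records))
```

```
Within-subject repeatability of repeated measurements
  n = 39 canals, N = 121 measurements, K in {2, 3, 4, 5} (effective K 3.095)
  mean 0.790, range [0.098, 2.130]
  wSD 0.313, RC 0.868
```

Thirty-nine canals (20 patients × 2 sides, minus one canal the simulated
system dropped) were measured 121 times in total; the SMCD of a canal
varies with within-subject standard deviation 0.313 mm, so two repeated
localisations of the same canal are within 0.868 mm of each other with
95% confidence.

```r
ratings <- simulate_likert(cohort$manifest, cfg$rater_truth, seed = 7)
fit <- fit_pcm(ratings, marker = "dls", seed = 7,
               chains = 4, warmup = 1000, iter = 1000, rhat_max = 1.2)
rm_posterior(fit)
```

```
Repeatability measure (posterior mean and 95% CrI), marker: dls
   rater  mean lower upper
 expert1 0.902 0.834 0.954
 expert2 0.777 0.696 0.855
 expert3 0.843 0.765 0.905
 average 0.841 0.800 0.876
```

An across-expert RM of 0.84 means a simulated expert re-rating the same
segmentation gives the identical score about 84% of the time, with the
credibility interval quantifying posterior uncertainty from the finite
rating sample.

A command-line front end over the same functions (subcommands `simulate`,
`metrics`, `repeatability`, `likert-rm`, `report`) is installed at
`inst/cli/canalrepro.R`.

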