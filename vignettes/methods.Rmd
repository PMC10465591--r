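---
title: "Methods: repeatability of repeated mandibular canal localisations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability of repeated mandibular canal localisations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An automated system localises the mandibular canal — the bony channel
carrying the inferior alveolar nerve from the mandibular foramen
(posterior) to the mental foramen (anterior) — as a 3D centerline in cone
beam CT scans. Because patients are often scanned repeatedly, the clinically
relevant question is not only how close the automated centerline is to an
expert's annotation on one scan, but how *stable* that agreement is across
repeated scans of the same patient. This package implements that
repeatability analysis end to end: geometric agreement metrics, a
within-subject variance model for the repeated distances, and a Bayesian
repeatability measure for ordinal quality ratings. The two canals (left,
right) of a patient are always treated as independent subjects of interest
and never pooled across sides.

The clinical data this kind of analysis runs on is access-restricted, so
the package also ships a synthetic cohort generator with known ground
truth; every stage of the pipeline is exercised and tested against the
generating parameters.

# Agreement metrics

**SMCD.** The symmetric mean curve distance between two centerlines: each
curve is resampled at uniform arc length (default step 0.5 mm), the mean
exact point-to-polyline distance (minimum over segments, not vertices) to
the other curve is computed in both directions, and the two directed means
are averaged. The exact sampling convention of the metric's original use
is not recoverable, so the step is a parameter; 0.5 mm is much finer than
the 3 mm annotation interval, which makes the value resolution-stable (the
test suite checks agreement within 1% against a 10,000-point dense-sampling
oracle). Truncated outputs are *not* trimmed before comparison: a
centerline that stops short of a foramen is penalised by the SMCD, in line
with "short at the foramen" being a scored error rather than an excluded
region.

**Tube masks, DSC, ASSD.** Approximate segmentations are produced by
expanding a centerline into a 1.5 mm diameter tube: a voxel is foreground
exactly when its centre lies within the radius (default 0.75 mm) of the
polyline. Coordinates follow the voxel-centre convention with 0-based
indices (world = origin + index × spacing); anisotropic spacings are
respected everywhere. The Dice coefficient is `2|A∩B|/(|A|+|B|)`. For the
average symmetric surface distance, the surface is defined as foreground
voxels with at least one six-connected background (or out-of-bounds)
neighbour, and distances are Euclidean distances between surface voxel
centres in millimetres — no sub-voxel surface meshing, which keeps the
metric deterministic and checkable against an exhaustive all-pairs oracle.

**Mask-to-centerline.** `centerline_from_mask()` is deliberately modest
plumbing for round-trip tests (voxelize a curve, recover it, compare): per
26-connected component it finds the two geodesic extremes of the voxel
graph and connects them with a shortest path whose edge costs are biased
toward voxels that survive more iterations of 6-connected peeling, so the
path tracks the medial axis of a tube. It is not a general skeletonisation
and makes no claim about the postprocessing used by any particular
segmentation system. The round-trip SMCD is below one voxel spacing at the
0.2, 0.3 and 0.4 mm spacings the tests use.

# Within-subject repeatability of SMCD

For canal *i* with `K_i` repeated measurements `Y_ik`, the within-subject
mean square pools squared deviations from the canal means,

WMS = Σᵢ Σₖ (Y_ik − Ȳᵢ)² / (n (K − 1)),

with the *effective* replicate count K = (N − ΣK_i²/N)/(n − 1) applying a
downward correction for unbalanced designs (it collapses to k when every
canal has exactly k replicates). Then wSD = √WMS and the repeatability
coefficient RC = 1.96·√2·wSD, the 95% bound on the difference between two
repeated measurements of the same canal. Canals with a single valid
measurement are excluded from WMS but retained in descriptive summaries,
and the two counts are reported separately. Negative measurements are
rejected, not clipped — distances cannot be negative, so a negative value
indicates an upstream bug.

Descriptive summaries are median and IQR with linear-interpolation
quantiles (`stats::quantile()` type 7) or mean and SD with denominator
n − 1. Both conventions are pinned purely for reproducibility of the
printed tables; nothing downstream depends on the choice. The mean column
of the repeatability table is the mean over all included measurements (not
the mean of per-canal means); with unequal `K_i` the two differ, and the
convention had to be fixed one way.

# The ordinal repeatability measure

Quality ratings are on a 0–4 Likert scale (3–4 = diagnostically fully
usable; internally mapped to 1–5). Because the ratings are discrete,
heavily top-concentrated, and the replicate structure is unbalanced,
Gaussian random-effects or rank-correlation approaches are not appropriate;
instead the package models rater behaviour with a partial credit model with
subject random effects:

p(y = h | x, α_j, δ_j) ∝ exp( Σ_{m<h} α_j (x − δ_{jm}) ),

with latent segmentation quality `x_i`, per-rater discrimination `α_j > 0`
and step thresholds `δ_jm`. The repeatability measure of rater *j* is the
probability that two independent ratings of the same segmentation
coincide, averaged over subjects:

RM̂_j = (1/n) Σᵢ Σₕ p(yᵢ = h | xᵢ, α_j, δ_j)²,

which lives in [1/H, 1]: 1/H for a completely uninformative rater
(α = 0), 1 for a deterministic one, and is non-decreasing in α.

**Priors and sampling.** The original formulation of this measure defers
its implementation details to supplementary material, so the package fixes
its own explicit, weakly informative choices: x ~ Normal(0,1) (anchoring
the latent location and scale, which identifies α and δ),
α_j ~ LogNormal(0,1), δ_jm ~ Normal(0,2²). The joint posterior is sampled
with JAGS; defaults are 4 chains × 1,000 warmup + 1,000 retained
iterations. RM̂_j is evaluated at every posterior draw (using that draw's
subject effects), and reported as the posterior mean with a central 95%
credibility interval, per rater and for the across-rater average — the
average is the per-draw mean of the rater values, so its interval reflects
the joint posterior rather than combining marginal intervals. Fits are
computed per marker (expert-annotated vs automatically produced
segmentations are separate models) on session-1 scores, and the binary
diagnostic-suitability analysis refits the same model with H = 2 on
binarized scores.

**Convergence.** The fit computes split-chain R-hat for every monitored
parameter and gates on the structural rater parameters (α, δ) plus their
effective sample size; the per-subject effects are nuisance parameters
entering RM only through an average over subjects. The default gate
(R-hat ≤ 1.01, ESS ≥ 100) is deliberately strict and appropriate for
production-length chains; reduced-scale runs (short chains in tests and
worked examples) pass an explicitly relaxed gate, and the refusal to
summarise a non-converged fit must be overridden explicitly. A rater whose
scores are all in one category makes α unidentifiable; such raters are
excluded from the MCMC with a warning and reported at the deterministic
limit RM = 1.

**Aggregation rules.** Median expert ratings use the midpoint convention
for even counts, giving the three-way classification fully (median ≥ 3) /
uncertain (2 < median < 3) / not fully (median ≤ 2). Error-type majority
voting is strict: a type is kept only when reported by more than half of
the experts, and an exact tie (possible only with an even number of
experts) is excluded — with three experts ties cannot arise, so the rule
had to be fixed here.

# The synthetic cohort generator

The generator reproduces the study *structure*, not any patient's data:
72 patients, 2–5 scans each (54% with exactly two; the 3/4/5 split is
20/15/11%, chosen once since only the two-vs-multiple split is stated for
such cohorts), two canals per scan, and four heterogeneity groups (normal
32%, TMJ prosthetic 18%, orthognathic 30.5%, pathological 19.5%). Canal
templates are smooth chord-length splines through anatomy-shaped knots
running mental-foramen-first, 55–75 mm long with control points at 3 mm
spacing, mirror-symmetric across the sagittal plane up to per-patient
jitter (SD 1.5 mm).

A repeated scan perturbs the template with a smooth correlated
displacement field (squared-exponential correlation along the arc,
correlation length 10 mm). The SMCD of such a field has no closed form in
its amplitude, so the amplitude is calibrated empirically: a Monte-Carlo
factor (expected SMCD per unit amplitude, cached per correlation length)
gives the first guess, and in `exact` mode one secant step rescales the
realised field so the achieved SMCD matches the target within about 1%.
Per-scan targets are drawn as truncated-normal values around a per-canal
mean, with per-group means (0.72–0.81 mm) and within-canal SDs (0.12–0.62
mm) set to the values reported for the four heterogeneity groups in this
kind of cohort, so the generated quantitative tables have realistic
magnitudes. Radiologist-role curves get small independent annotation noise
(0.05 mm). Canals drop out (the automated system finds nothing) with
probability 0.03 and are truncated at a random foramen with probability
0.05 (2–8 mm), populating the invalid-record and error-type paths.

Ratings are drawn from the partial credit model itself with three
simulated experts whose discriminations (3.0/2.2/1.8 for the expert-
annotation marker, 2.2/1.8/1.5 for the automated one) and thresholds put
the generating RM in the 0.85–0.96 range and the mean score near 3.9 —
the top-heavy regime this analysis is designed for. Dropped canals are
scored 0 with `fully_missing`; truncated ones attract the matching
`short_*` error type; the two clinically relevant types are attached only
to scores 0–2, as the rating protocol requires.

Randomness is organised as named substreams (cohort, perturbation,
ratings) derived from one master seed, so each stage can be regenerated
independently and every artifact is bit-reproducible under the same seed.

**What the generator does not emulate:** CBCT intensities, metal
artefacts, anatomical variation beyond smooth canal-like arcs, and
rater drift between sessions (session effects are exactly exchangeable by
construction). Passing recovery tests therefore demonstrates that the
estimators recover the parameters of this statistical structure — not
that any particular clinical system achieves those values on real scans.

# Numerical choices and degenerate inputs

* Duplicate consecutive control points are merged with a warning rather
  than rejected; curves with fewer than two distinct points are errors.
* A tube voxelization that produces no foreground voxel (curve outside
  the grid) is signalled, never returned silently.
* DSC of two empty masks and ASSD with any empty mask are errors, as is
  any grid mismatch (shape, spacing, origin).
* Nearest-surface distances use a BLAS-friendly expansion of the squared
  distance, which can leave ~1e-7 mm of numerical dust where an exact
  zero is expected; tests compare accordingly.
* Canal validity defaults to output-exists (a canal is invalid only when
  the automated system produced nothing); an optional SMCD threshold can
  additionally invalidate canals, since published analyses do not pin
  this policy down.
* Curve tables round-trip through delimited text at ~15 significant
  digits (R's `write.csv`), which is reproducible but half an ulp short
  of bit-exact; tests compare at 1e-12 mm.

# Problem sizes used in tests and the worked example

Tests run the geometry oracles on small random instances, the wSD
recovery on 100 patients (≥ 200 replicated canals), and the RM recovery
on 10 replicate datasets of 2 raters × 150 subjects with 4 short chains
(warmup 1,000, 1,200 retained draws) — sizes chosen so the whole suite
exercises every estimator at meaningful precision in a few minutes on one
core. The accompanying reproduction script runs a 40-patient cohort with
the same design (roughly 190 canal-scans) through the complete pipeline,
including tube-mask DSC/ASSD at the sampled 0.2–0.4 mm spacings and four
posterior fits (two markers × two scales) with moderately shortened
chains; the cohort size and chain lengths are the package's choice of a
desk-scale configuration at which every stage, including the slowest
posterior fit, completes in a few minutes.
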