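---
title: "Subtraction ictal-interictal SPECT analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtraction ictal-interictal SPECT analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siscom)
```

## The problem

In pharmacoresistant focal epilepsy, surgical treatment requires localizing
the epileptogenic zone (EZ) — the cortical region whose removal can abolish
seizures. Brain-perfusion SPECT exploits the perfusion increase that a seizure
produces at its onset zone: a radiotracer injected at seizure onset
(*ictal* scan) freezes a snapshot of seizure-time perfusion, which is compared
with a baseline (*interictal*) scan. Reading the two scans side by side is
hard when the hyperperfusion is subtle; subtraction analysis (SISCOM) makes
the comparison quantitative.

This package implements the subtraction pipeline end to end, a
phantom simulator that provides ground truth for validating it, and the
agreement statistics used to compare an imaging localization against a
clinical reference standard.

## The pipeline

Given an ictal volume $I$ and an interictal volume $J$ (NIfTI, RAS+ world
coordinates via each header's affine), `runSiscom()` composes:

1. **Brain mask.** Voxels at or above `maskFraction` (default 0.3) times the
   robust maximum (99th-percentile intensity) of the ictal volume, reduced to
   the largest 26-connected component, holes filled. The robust quantile makes
   the mask invariant to positive intensity rescaling; perfusion tracers
   concentrate in brain tissue, so an intensity threshold is the standard
   operational definition of "all brain voxels".
2. **Rigid registration** of $J$ to $I$ by mutual-information (MI)
   maximization. The metric is joint-histogram MI with `nBins = 32` bins per
   axis over within-mask voxels. The optimizer is Nelder-Mead over the six
   rigid parameters (rotations about the world axes applied x
   $\rightarrow$ y $\rightarrow$ z about the fixed-mask centroid, then
   translation), on a fixed 4x / 2x / 1x multiresolution schedule,
   initialized at identity, with simplex restarts at each level until the
   metric improves by less than `minImprove` = 1e-4 nats (at most
   `maxRestarts` = 10 rounds). Both volumes serve as source and target: the
   forward estimate is averaged with the inverted reverse estimate in the
   six-parameter space, which symmetrizes the bidirectional realignment.
   The mask centroid stands in for an anatomical reference point (the
   anterior commissure in clinical practice) because no anatomy is available
   to the algorithm.
3. **Resampling** of $J$ onto $I$'s grid with trilinear interpolation
   (nearest-neighbour for label volumes). Voxels mapped from outside $J$'s
   support are zero and removed from the analysis mask.
4. **Whole-brain normalization**: each volume is scaled so its within-mask
   mean equals `targetMean` (default 100, arbitrary: the z map is invariant
   to it). This removes the global uptake difference between injections.
5. **Subtraction**: $D = I_\mathrm{norm} - J_\mathrm{norm}$ inside the mask.
6. **z-scoring**: $z = (D - \bar D)/s_D$ with mean and sample standard
   deviation (n-1) taken over all brain voxels. By construction the z map has
   within-mask mean 0 and SD 1.
7. **Thresholding and clustering.** Voxels *strictly exceeding*
   `zThreshold` (default 2) are significant hyperperfusion. 26-connected
   components smaller than `minClusterVoxels` (default 5) are discarded.
   Clusters are ordered by descending peak z; ties break toward the larger
   cluster, then the lexicographically smallest peak voxel index, giving a
   total, deterministic order.
8. **EZ call.** The top-ranked cluster is the EZ candidate; all others are
   propagation areas. When more than one cluster is present the call carries
   a review flag: clinically, multiplicity is adjudicated with the
   radiotracer injection time and the clinical picture, a judgment this
   package does not automate. An empty cluster list is a valid
   "no significant hyperperfusion" result, not an error. With an atlas, each
   cluster is attributed to the lobe under its *peak* voxel (the highest-z
   rule for clusters spanning several lobes), and laterality comes from the
   sign of the peak's world x coordinate.

### Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `zThreshold` | 2 | z | significance cut; strict inequality |
| `minClusterVoxels` | 5 | voxels | suppresses single-voxel noise clusters |
| `connectivity` | 26 | — | cluster and mask component neighbourhood |
| `maskFraction` | 0.3 | fraction | of the 99th-percentile robust maximum |
| `targetMean` | 100 | intensity | normalization target; z map invariant |
| `nBins` | 32 | — | MI joint histogram resolution |
| `schedule` | 4, 2, 1 | factor | multiresolution downsampling |
| `doRegister` | TRUE | — | disable for pairs already on one grid |

All defaults live in `siscomConfig()` and serialize to YAML
(`saveConfig()` / `loadConfig()`); command-line flags override them.

## Numerical choices

- **Sample SD (n-1)** in the z map: the usual statistical-software default;
  at brain-voxel counts (~10^4) the distinction from the population SD is
  far below any decision threshold.
- **Strict inequality** at the z threshold: a literal reading of
  "exceeding"; the measure-zero boundary case is pinned for testability.
- **Tie-breaking** of equal peak z by size then lexicographic peak index
  makes cluster order total and reproducible across platforms.
- **Identity snap in registration**: when the optimized metric does not beat
  the identity initialization by more than 1e-6 nats, the exact identity is
  returned. For already-aligned inputs the identity is a sharp optimum that
  interpolation blur prevents any optimizer from reaching; snapping makes
  the aligned, focus-free, noise-free case propagate to the exact
  "degenerate difference" error, confirming the pipeline adds no hidden
  asymmetry. The returned metric is never below the identity metric.
- **Degenerate inputs** error loudly and name their stage: constant volumes
  (no mask contrast), identical pairs (zero-SD difference), empty masks,
  non-overlapping volumes.
- **Only hyperperfusion** (z > threshold) enters the EZ call;
  `reportHypo = TRUE` additionally reports z < -threshold clusters for
  inspection, since the interictal scan often shows the EZ as hypoperfused.

## The phantom simulator

`simulateCase()` provides the ground truth the clinical data cannot: the
true focus location. It emulates the statistical structure the analysis
relies on:

- an ellipsoidal brain (semiaxes 60 x 75 x 55 mm) on a 40 x 48 x 40 grid at
  4 mm spacing — realistic SPECT sampling;
- a smooth baseline perfusion pattern: a fixed low-order polynomial
  modulation of ±10% around the baseline of 100 counts, so backgrounds are
  never trivially constant;
- focal hyperperfusion: spheres with relative amplitude $(1 + a)$, default
  one left-temporal focus with $a = 0.4$ and radius 8 mm;
- effective resolution: Gaussian PSF of 7.65 mm FWHM, the reconstruction
  filter width of a clinical perfusion-SPECT protocol;
- post-reconstruction noise: Gaussian with SD = 5% of baseline by default
  (noise after iterative reconstruction plus smoothing is approximately
  Gaussian); a Poisson option gives raw-count flavour;
- patient repositioning: an optional rigid misalignment applied to the ictal
  volume, with the focus centres reported both in the canonical frame and
  mapped into the ictal frame where the analysis output lives;
- full reproducibility from an integer seed, without disturbing the
  caller's RNG stream.

A deterministic geometric atlas (`makeSyntheticAtlas()`) partitions the
ellipsoid into left/right frontal, temporal, parietal, occipital and insular
pseudo-lobes, mirror-symmetric in x, so lobe attribution can be tested
against construction.

What the phantom does **not** emulate: anatomy (gyri, ventricles, asymmetric
hemispheres), attenuation and scatter, projection-domain reconstruction
artifacts, and perfusion changes that are not focal spheres. Passing the
phantom suite therefore demonstrates the pipeline's correctness under its own
model assumptions — recovering known foci through noise, blur and
misalignment — not clinical sensitivity on real patients.

### Validation problem sizes

The shipped checks use 20 simulated cases for focus recovery (one +40%,
8 mm focus, 5% noise, 4 mm misalignment each), 20 random rigid perturbations
(up to 10 mm / 10°) for registration recovery, 10 pairs for the z-map moment
and scale-invariance contracts, 100 random 16³ maps against a union-find
clustering oracle, and full enumeration of the exact Mann-Whitney
distribution for all group sizes with n + m ≤ 10. These sizes give stable
pass/fail behaviour while keeping a full run of the suite to a few minutes.

## The study table and agreement statistics

The package ships a 23-patient table (`studyTableFixture()`): reference EZ
side and lobe(s), radiotracer injection time (one patient unrecorded), and
the concordance label of each method (visual reading and subtraction
analysis) against the reference standard — `concordant` (the localization
overlaps the full EZ), `partially_concordant` (some but not all foci of a
multifocal EZ found) or `discordant` (nothing found, or a different lobe).
It is data, never regenerated.

`summarizeTable()` reports per-label counts and percentages at one decimal.
Percentages use largest-remainder rounding so each method's three
percentages sum to 100.0 — the convention that reproduces the published
breakdown exactly (plain half-up rounding is also reported as `pct_raw`;
the two differ only for the visual partially-concordant category, 13.1 vs
13.0).

`cohenKappa()` implements $\kappa = (p_o - p_e)/(1 - p_e)$ directly;
`mcnemarTest()` offers the exact binomial form (two-sided, success
probability 1/2 on the discordant pairs, capped at 1) and both chi-square
forms. How the study dichotomized partially-concordant labels for its paired
test is not recoverable, so `compareMethodsMcnemar()` computes all three
defensible rules (partial as concordant, partial as discordant, partial
excluded) and labels each explicitly; none of them is asserted against the
published p-value. `mannWhitney()` wraps the rank-sum test: exact for
combined samples of 12 or fewer without ties, normal approximation with tie
correction otherwise; the tests verify the exact branch against full
enumeration of group assignments.

## Known limitations

- Rigid registration only; no spatial normalization to a template and no
  deformable correction. Pairs from the same patient days apart are the
  intended use.
- The brain mask is intensity-based; severe hypoperfusion touching the
  mask threshold could erode it. The fraction is exposed for such cases.
- Lobe attribution is as good as the supplied atlas; the synthetic atlas is
  for validation, not anatomy.
- The EZ call automates the highest-peak rule only; multi-cluster cases are
  flagged for human review rather than resolved.
- MI registration assumes the two volumes view the same anatomy with
  overlapping support; fields of view that barely intersect will fail loudly
  (`converged = FALSE` or a no-overlap error), not silently.

## A worked example

```{r example, eval = FALSE}
library(siscom)

sim <- simulateCase(phantomSpec(
  seed = 11L,
  misalignment = rigidTransform(translations = c(4, 0, 0))))

res <- runSiscom(sim$ictal, sim$interictal, atlas = sim$truth@atlas)
res$ez
clusterTable(res$clusters)

# against ground truth
sqrt(sum((res$ez@primary@peakWorld - sim$truth@focusCentersIctal[[1]])^2))
```
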