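# siscom

Subtraction ictal–interictal SPECT analysis for localizing the epileptogenic
zone (EZ) in focal epilepsy, with a validated phantom simulator and the
agreement statistics used to compare imaging localizations against a clinical
reference standard.

## Who this is for

Epilepsy-imaging researchers and nuclear-medicine analysts who have paired
ictal/interictal brain-perfusion volumes (NIfTI) and want a reproducible,
scriptable subtraction analysis — plus a way to validate the whole chain on
synthetic cases with known ground truth.

## The method

A radiotracer injected at seizure onset freezes seizure-time perfusion; the
interictal scan provides the baseline. With ictal volume *I* and interictal
volume *J*:

1. brain mask from *I* (≥ 0.3 × 99th-percentile intensity, largest
   26-connected component, holes filled);
2. rigid registration of *J* to *I* by mutual-information maximization
   (32-bin joint histogram, Nelder–Mead with restarts on a 4×/2×/1×
   multiresolution schedule, symmetrized over both registration directions);
3. whole-brain normalization of both volumes to a common within-mask mean;
4. voxel-wise difference *D* = *I*ₙ − *J*ₙ, standardized over all brain
   voxels: *z* = (*D* − mean *D*) / SD *D*;
5. voxels with *z* > 2 are significant hyperperfusion; 26-connected clusters
   (≥ 5 voxels) are ranked by peak *z*;
6. the top cluster is the EZ candidate, the rest are propagation areas;
   multi-cluster calls carry a review flag, and lobe attribution follows the
   cluster's peak voxel in a supplied atlas.

The phantom module simulates SPECT-like pairs (ellipsoidal brain, smooth
baseline, spherical foci of known amplitude and location, 7.65 mm FWHM
Gaussian PSF, Gaussian or Poisson noise, optional rigid misalignment) so
every stage can be tested against ground truth. The statistics module ships a
23-patient study table and implements the three-way concordance
classification, Cohen's kappa, the exact and chi-square McNemar tests, and
the exact Mann–Whitney test.

## Worked example

```r
library(siscom)

# a simulated case: +40% left-temporal focus, 8 mm radius, 5% noise,
# 4 mm patient repositioning between the two scans
sim <- simulateCase(phantomSpec(
  seed = 11L,
  misalignment = rigidTransform(translations = c(4, 0, 0))))

res <- runSiscom(sim$ictal, sim$interictal, atlas = sim$truth@atlas)
res$ez
#> EZCall: 4 cluster(s) [multiple clusters - review]
#>   primary: Cluster: 50 voxels (3.20 mL), peak z 6.997 at voxel (11,25,15), left temporal
#>   propagation: Cluster: 5 voxels (0.32 mL), peak z 2.706 at voxel (28,24,30), right parietal
#>   propagation: Cluster: 5 voxels (0.32 mL), peak z 2.643 at voxel (17,21,10), left temporal
#>   propagation: Cluster: 5 voxels (0.32 mL), peak z 2.629 at voxel (20,19,13), right temporal

sqrt(sum((res$ez@primary@peakWorld - sim$truth@focusCentersIctal[[1]])^2))
#> [1] 3.741657   # mm from the true focus centre, within one voxel diagonal
```

The primary cluster lands 3.7 mm from the simulated focus centre and is
attributed to the left temporal lobe; the three small propagation-area
clusters are noise at the significance boundary, which the review flag
surfaces. On the packaged study table:

```r
summarizeTable(studyTableFixture(), "siscom")
#>                  label  n  pct pct_raw
#> 1           concordant 18 78.3    78.3
#> 2 partially_concordant  1  4.3     4.3
#> 3           discordant  4 17.4    17.4
```

The subtraction analysis is concordant with the reference standard in 18 of
23 patients (78.3%) versus 13 of 23 (56.5%) for visual reading — a
21.8-percentage-point gain.

## Command line

```sh
Rscript inst/cli/siscom.R simulate --seed 7 --out case/
Rscript inst/cli/siscom.R run --ictal case/ictal.nii.gz \
    --interictal case/interictal.nii.gz --atlas case/atlas.nii.gz --out out/
Rscript inst/cli/siscom.R concordance \
    --table inst/extdata/study_table_23pt.tsv --method siscom
```

`run` writes the z map (NIfTI), the cluster table (TSV), the estimated
transform (plain text) and a provenance record (YAML: config, input digests,
versions).

## Package layout

- `R/` — S4 classes (`BrainVolume`, `BrainMask`, `RigidTransform`,
  `ZScoreMap`, `Cluster`, `EZCall`, …), the pipeline, the simulator, the
  statistics, the CLI.
- `src/` — Rcpp kernels for trilinear resampling and the fused
  registration metric.
- `inst/extdata/study_table_23pt.tsv` — the packaged per-patient table.
- `vignettes/siscom-methods.Rmd` — model, assumptions, parameter rationale,
  numerical choices and limitations.
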