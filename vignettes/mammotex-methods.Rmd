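---
title: "Texture-based mammography CAD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based mammography CAD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotex)
library(dplyr)
```

## The problem and the pipeline

Computer-aided diagnosis (CAD) of screening mammograms asks two binary
questions of every image: does it contain a lesion (normal vs abnormal),
and if so, is the lesion benign or malignant? `mammotex` implements the
classical texture-analysis route to both answers as one reproducible
pipeline:

1. **Artifact removal** — film labels are bright, disconnected marks;
   thresholding + morphological opening + largest-component selection
   isolates the breast.
2. **Enhancement** — five combinations of a median filter (MF), contrast
   limited adaptive histogram equalization (CLAHE) and unsharp masking
   (USM): `CLAHE`, `MF&CLAHE`, `MF&USM`, `CLAHE&USM`, `MF&CLAHE&USM`.
3. **Segmentation** — k-means on pixel intensities with k = 3 separates
   background, breast tissue and the pectoral muscle; the pectoral wedge is
   removed and a square region of interest (ROI) is cut around the lesion
   (or around dense tissue, for normal cases).
4. **Texture features** — 22 gray-level co-occurrence matrix (GLCM)
   features and 11 gray-level run-length matrix (GLRLM) features, computed
   at 0°, 45°, 90° and 135° and averaged over angles: 33 features per ROI.
5. **Selection** — features with pairwise |Pearson r| > 0.90 are
   eliminated greedily; per-feature ROC AUC screens univariate value. A
   fixed nine-feature preset (autocorrelation, contrast, cluster
   prominence, entropy; SRE, LRE, GLN, SRLGE, LRLGE) is available for
   replication-style runs.
6. **Classification** — SVM, random forest, neural network, k-NN, naive
   Bayes and a decision tree, on a stratified 70/30 case-level split, with
   accuracy, sensitivity, specificity, PPV, NPV, AUC, balanced accuracy
   and F1 per classifier × combination.

Everything runs on synthetic phantom mammograms with ground-truth masks,
so the full analysis is testable without downloading any image database;
real mini-MIAS files are accepted through the same PGM/metadata readers.

## The synthetic phantom

The generator emulates the geometry of a mediolateral-oblique film: a
near-black background (intensity ≈ 5), a half-elliptical breast attached
to the chest-wall side (base intensity 110 plus one low-frequency Gaussian
texture field), a brighter pectoral wedge in the upper chest-wall corner
(≈ 180), a ≥ 240 label rectangle in a background corner, and an optional
lesion. Benign lesions are smooth cosine-profiled discs; malignant lesions
are star-shaped spiculated blobs (default 8 arms, boundary radius
oscillating between 0.45 r and r) with additive internal speckle
(sd = 0.25 × contrast). Separability between benign and malignant is
therefore carried by *shape and texture*, not merely by brightness — the
property the GLCM/GLRLM features are designed to capture. Contrast and
spicule count are the difficulty dials.

Study conditions are fixed once in the generator defaults: image side 1024
(the source database geometry; cohort runs use 256 for tractability, since
side length is an explicit parameter), lesion radius 4–7 % of the side,
peak contrast 50–80 intensity units (an "easy", high-contrast regime),
Gaussian noise sd 3, salt-and-pepper probability 0 (available as a dial
for the median-filter property checks). Consecutive cases are paired as
the two lateralities of one subject, which the splitter respects.

What the phantom does **not** model: X-ray physics (scatter, beam
hardening), parenchymal ductal structure, microcalcification clusters, and
density categories. Passing tests on phantoms therefore demonstrates that
the pipeline's machinery is correct and that it recovers a known planted
signal; it does not certify clinical performance on real mammograms.

## Numerical definitions and conventions

- **Raster convention.** Top-left origin, x = column, y = row. The
  mini-MIAS info file's bottom-left y is flipped on ingest
  (`y = height − 1 − y_file`). Only 8-bit PGM is supported.
- **Operator order in combinations** follows the name left-to-right
  (smooth → contrast → sharpen); the double combinations inherit the order
  implied by their names.
- **Filter parameters** (none are dictated by the benchmark design, so all
  are explicit configuration, echoed into every run log): median window
  3×3; CLAHE clip 0.01 — the fraction of a tile's pixels one histogram bin
  may hold — on an 8×8 tile grid; USM sigma 2 px, amount 1; Otsu label
  threshold; opening disc radius 5 px. All neighbourhood operators use
  reflection padding.
- **k-means.** Lloyd's algorithm on scalar intensities; centroids start at
  evenly spaced quantiles (deterministic, avoids empty clusters);
  equidistant pixels go to the lower-index cluster; an emptied cluster is
  re-seeded at the point farthest from its centroid; tol = 1e-4 intensity
  units, max 100 iterations. The objective J (within-cluster sum of
  squares) is non-increasing by construction and is asserted per run.
  Pixels outside the breast mask join the lowest-intensity (background)
  cluster. Pectoral removal zeroes only the connected component of the
  corner-touching cluster, never the whole cluster, so a bright lesion
  sharing the cluster is untouched.
- **ROIs.** Patch side 128 at full resolution (32 at side 256 — kept
  proportional); the benchmark design does not specify the ROI rule for
  normal images, so we centre their patch on the centroid of the brightest
  remaining cluster, a comparable dense-tissue sample. Abnormal cases
  without recorded lesion geometry are logged and skipped.
- **Texture.** Quantization to Ng = 8 levels, uniform over the in-mask
  range (range-relative, hence invariant to adding a constant); GLCM
  distance d = 1; symmetric accumulation; features per angle, then the
  arithmetic mean over the four angles. Logs are base 2 with 0·log 0 = 0;
  the information-measure denominators are guarded by max(HX, HY, 1e-12);
  sum variance is taken about the sum average and difference variance is
  the variance of the difference distribution; GLRLM gray levels are
  indexed from 1 so low-gray-level weights stay finite; run percentage is
  Nr/Np. A degenerate marginal (sd = 0) defines the correlation-type
  features as 0 with a warning.
- **Selection.** "Correlation above 0.90" is read as |r| > 0.90 —
  anticorrelated duplicates are equally redundant. Elimination scans the
  canonical feature order with a keep-first policy. In pipeline mode the
  filter is fit on the training split only, to avoid leakage; the
  nine-feature preset bypasses data-driven selection for replication runs.
- **Evaluation.** The benchmark design names both a 70/30 split and
  leave-one-out cross-validation without relating them; we report held-out
  test metrics by default, offer LOOCV within the training split for model
  assessment (`loocv_scores()`), and expose a pure-LOOCV report mode. AUC
  is the midrank Mann–Whitney statistic; ratios with zero denominators are
  reported as missing, never as 0. Positive classes: abnormal, then
  malignant. Classifier defaults (RBF SVM C = 1, γ = 1/p; 500 trees; one
  hidden layer of 16; k = 5; Gaussian naive Bayes; CART) are configuration,
  standardizing features with training statistics for SVM/ANN/k-NN.
- **Determinism.** A single top-level seed deterministically derives every
  stage seed; identical configurations yield bit-identical images and CSV
  reports.

## Problem sizes used by the tests and the acceptance script

Oracle-equivalence checks (brute-force pair/run enumeration, exhaustive
Mann–Whitney counting, exhaustive contiguous-partition k-means) run on 100
random grids up to 12×12, score vectors up to n = 30 and toys up to 16
pixels. The simulation-recovery check uses a 120-case cohort (60 normal /
30 benign / 30 malignant) at side 256 with patch 32 under `CLAHE&USM`,
chosen as a cohort size at which split AUCs are stable while the whole
suite stays comfortably interactive; the factorial report-shape check uses
40 cases at side 192. The acceptance script regenerates all of these from
scratch from its `--seed`.

```{r example, eval = FALSE}
co <- generate_cohort(20, 10, 10, seed = 1, size = 256)
rep <- run_experiment(co, "normal_abnormal", combos = "CLAHE_USM",
                      patch_size = 32, selection = "table1")
tidy(rep)
autoplot(rep)
```

## Interfaces

The package is function-first: the exported functions, this vignette and
`scripts/acceptance.R` are the interface. `run_all(run_config(...))`
orchestrates an end-to-end run — phantom cohort, per-combination feature
CSVs, a selection report, per-task metric tables and AUC plot data, plus a
line-per-event log — so a shell user needs exactly one `Rscript -e` call;
no separate CLI binary is shipped.

## Known limitations

- Phantom realism, as above; headline metric values on phantoms say
  nothing quantitative about real mammograms.
- Scalar-intensity k-means cannot separate structures of equal brightness;
  the extension point (intensity, x, y) is left open.
- The canonical 22-feature GLCM set is one established enumeration of the
  extended Haralick family; other toolboxes order or name members
  differently, which matters when comparing feature tables across
  software.
- No multiple-testing control is applied to per-feature AUC screening;
  the reports are descriptive.
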