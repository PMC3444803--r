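---
title: "Volumetric texture classification with LBP-TOP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric texture classification with LBP-TOP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbptop)
```

## The model

The local binary pattern (LBP) operator encodes the local intensity
*ordering* around each pixel.  For a center value $v_c$ and $P$ neighbors
$v_0, \dots, v_{P-1}$ sampled at radius $R$,

$$\mathrm{LBP}_{P,R} = \sum_{p=0}^{P-1} s(v_p - v_c)\, 2^p, \qquad
s(x) = \begin{cases}1 & x \ge 0\\ 0 & x < 0\end{cases}$$

so each code is a $P$-bit word describing which neighbors are at least as
bright as the center.  A histogram of codes over a region is a texture
descriptor: each bin counts a "micro-texton" (edges, corners, spots,
ridges), and any morphological change shifts mass between bins.  Because
only the ordering of values enters, the codes are invariant to monotone
intensity transformations — scanner gain, bias-field-like rescaling —
which is exactly the property one wants for multi-site anatomical MRI.

For 3D volumes we use LBP on three orthogonal planes (LBP-TOP): the 2D
operator is applied independently in the xy, xz and yz planes through
every voxel, with the *same* radius on all three (isotropic LBP-TOP), and
the three per-plane histograms are concatenated.  A voxel contributes
only if its neighborhood fits inside the volume on all three planes.

**Uniform patterns.**  The uniformity $U$ of a code is its number of
circular bitwise transitions (including the wrap-around pair).  Codes
with $U \le 2$ — "uniform" patterns, which dominate natural images —
each keep their own bin, assigned in ascending code order; all remaining
codes share one catch-all bin.  For $P$ neighbors this gives
$P(P-1) + 3$ bins; for $P = 8$, $58 + 1 = 59$.  A whole-brain mask
therefore yields $3 \times 59 = 177$ features, a 116-region atlas
$20\,532$, and a 190-region atlas $33\,630$.

**Spatial context.**  Histograms can be pooled over a whole-brain mask or
per region of an atlas parcellation.  Region membership is decided by the
*center* voxel's label; neighbors may sample intensities outside the
region or mask, since the upstream registration is applied to whole-head
images and those intensities are real.

## Classification and feature selection

A linear SVM, $\hat{y}(x) = \mathrm{sign}(w^\top x + b)$, is the primary
classifier; a 1-nearest-neighbour classifier provides the
equal-feature-weight baseline.  Because $|w_j|$ measures the importance
of feature $j$ to the decision, the weights drive an iterative selection
over feature *groups* (e.g. one group per LBP radius, or per
parcellation): append the next group, grid-search the penalty $C$ by
internal 10-fold cross-validation, train, rank by $|w_j|$, keep the top
half (ceiling for odd counts), merge, repeat.  Whole-brain-scale groups
(a few hundred features) carry an explicit flag and are appended without
the drop step.  The survivor count follows the recurrence
$s_k = \lceil (s_{k-1} + n_k)/2 \rceil$, exposed as
`selection_cardinality()`.

Evaluation is by outer 10-fold cross-validation: fold assignment is a
seeded shuffle of the *sorted* subject ids (so a subject's fold depends
only on the id set and the seed), one fold held out per round, held-out
predictions pooled into a single accuracy and confusion matrix.  Feature
selection, when requested, runs inside each outer training split; running
it once on the full data before cross-validating inflates shuffled-label
accuracy well above chance, and the test suite keeps a regression test
for exactly that leak.

Significance is assessed two ways.  The permutation test re-runs the
pipeline on $k$ label-permuted copies and reports
$p = (\#\{e' \le e_{\mathrm{obs}}\} + 1)/(k + 1)$ with ties counted, so
the smallest attainable $p$ at the conventional $k = 100$ is
$1/101 \approx 0.0099$.  McNemar's test compares two classifiers through
their discordant predictions only.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `P` (neighbors) | 8 | the standard 2D LBP neighborhood; larger P explodes the bin count with no demonstrated gain for brain anatomy |
| `R_mm` (radius) | 1, 2, 3 mm as separate groups | texton scale on ~1 mm isotropic anatomy; radii are specified in mm and divided by the voxel spacing |
| `sampling` | `circular_interpolated` | the standard LBP\(_{P,R}\) circle with bilinear interpolation; `square` (integer offsets scaled by R) is provided because a 3x3-window variant is equally defensible |
| histogram `normalize` | TRUE (per region-plane L1) | regions differ in valid-voxel count across subjects; raw counts remain available (`normalize = FALSE`) |
| `C_grid` | $2^{-10} \dots 2^{10}$ | the usual powers-of-two liblinear sweep; ties go to the smallest C (strongest regularization) |
| CV folds | 10 outer, 10 inner | the conventional protocol for cohorts of a few hundred subjects |
| permutation `k` | 100 | resolution floor 1/101 on the p-value |

## The synthetic phantom world

`generate_phantom()` creates seeded 3D texture phantoms inside a central
ellipsoid "brain" mask, with a toy atlas partitioning the mask into
`n_regions` contiguous equal-count blocks.  Two texture families:

* `smoothed_noise` — Gaussian white noise smoothed with a class-dependent
  kernel width: class 0 at `base_sigma` (1 voxel), class 1 at
  `base_sigma + class_effect`.  The calibrated strong setting,
  `class_effect = 2` (widths 1 vs 3 voxels), changes the spatial
  autocorrelation — and hence the LBP code distribution — without
  touching the marginal intensity distribution's location.
* `fold_pattern` — a 3D sinusoidal lattice whose spatial frequency
  differs between classes, a cartoon of gyrification-frequency
  differences; `probability_map = TRUE` squashes it through a logistic
  into (0, 1) to emulate a gray/white/CSF probability map.

The signal is deliberately carried by texture *scale*, never by a mean
shift: monotone-intensity invariance makes additive offsets invisible to
the codes, so a generator that separated classes by brightness would
test nothing about the texture pipeline.  With `class_effect = 0` the two
class-conditional distributions are identical by construction, which is
what makes the null calibrations (chance-level accuracy, uniform
permutation p-values) meaningful.

What the phantoms do **not** emulate: real brain anatomy, inter-subject
registration error, intensity nonuniformity, site effects, or label
noise from heterogeneous diagnostic criteria.  A green synthetic test
establishes that the machinery measures what it claims on data whose
generating process is known — not that any particular clinical accuracy
is attainable.

## Numerical choices

* **Ties:** $s(0) = 1$ exactly; a neighbor equal to the center sets its
  bit, so a constant volume codes to $2^P - 1$ everywhere.
* **Interpolation:** bilinear interpolation uses the lerp (difference)
  form $v_{00} + f\,(v_{10} - v_{00})$, which is exact when the corner
  values coincide — the naive four-weight sum can round a constant
  neighborhood below the center value and silently clear bits.
* **Monotone invariance and interpolation:** an interpolated sample is a
  convex combination of four grid values, and a nonlinear increasing map
  does not commute with convex combinations, so under
  `circular_interpolated` sampling a code can legitimately change under
  e.g. `exp()`.  The invariance is exact for grid-aligned (`square`)
  sampling, which is how the test suite asserts it.
* **Boundary policy:** voxels whose neighborhood leaves the volume on any
  plane are invalid; nothing is padded, because padded intensities would
  be fabricated texture.
* **Neighbor convention:** neighbor $p$ sits at angle $2\pi p/P$ from the
  +first-axis direction, counter-clockwise, with bit weight $2^p$.  Any
  consistent convention yields equivalent features up to a bin
  permutation; fixing one makes bins comparable across runs and files,
  which is also why every loaded NIfTI volume is reoriented to a fixed
  canonical axis order before plane names mean anything.
* **Resampling** covers the same world extent and drops a trailing
  partial voxel rather than padding; trilinear interpolation is exact on
  affine intensity ramps (tested in closed form).  Label volumes resample
  nearest-neighbour only.
* **SVM solver:** dual coordinate descent on the L2-regularized L2-loss
  formulation, cyclic sweeps, tolerance $10^{-3}$ on the projected
  gradient (the liblinear-style default; tighten `tol` when weights
  themselves, not predictions, are compared).  The bias is a constant
  augmented feature.  The converged $w$ is unique (the primal is strictly
  convex), which is what makes selection reproducible across subject
  permutations.
* **Non-finite voxels** are a hard error on load; `on_nonfinite = "zero"`
  replaces them with 0 and warns with the count.

## Open design points, resolved

* The histogram-bin count for $P = 8$ is 59 (so 177 whole-brain
  features); a conflicting "259" figure in the source literature is
  treated as a typographical slip.
* Whether histograms are normalized per region is not fixed by the
  original protocol; the default here is per-(region, plane) L1
  normalization, with raw counts behind a flag.
* The C grid, SVM loss variant and fold stratification are likewise
  unspecified upstream: we use powers of two, L2-loss, and unstratified
  outer folds (a stratified option exists; *inner* grid-search folds are
  stratified to avoid degenerate single-class training splits at small
  n).
* Grid search is re-run at every selection iteration and, by default, in
  every permutation replicate; a fast path reuses the observed C when
  the $101$-fold cost matters.
* McNemar's test switches from the exact two-sided binomial to the
  continuity-corrected chi-square at $b + c = 25$; both paths can be
  forced.

## Limitations

Registration, skull stripping and tissue segmentation are upstream of
this package: inputs must already live on a common grid.  Only 3D scalar
NIfTI-1 volumes are supported.  The 1-NN baseline and linear SVM are the
only classifiers; rotation-invariant LBP variants and non-linear kernels
are out of scope.  Accuracies obtained on phantoms say nothing about
clinical discriminability — they validate the estimator, not the
hypothesis.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 42)          # 18^3, widths 1 vs 3 voxels
cohort <- generate_cohort(spec, 30)      # 60 subjects, balanced
feats <- extract_features(cohort$volumes, cohort$atlas, radii_mm = 1)
plan <- make_cv_plan(cohort$labels$subject_id, 10, seed = 7)
ev <- cross_validate(feats, cohort$y, plan, "svm")
ev$accuracy

pipe <- function(X, y) cross_validate(X, y, plan, "svm",
                                      C_grid = median(ev$fold_C))$accuracy
permutation_test(pipe, feats$X, cohort$y, k = 100, seed = 9)
```
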