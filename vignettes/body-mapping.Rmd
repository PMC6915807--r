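---
title: "Statistical body maps and avatar-based size perception: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical body maps and avatar-based size perception: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymapr)
```

## The measurement problem

Body image disturbance — a distorted perception of one's own body size,
shape or appearance — is central to anorexia nervosa and body dysmorphic
disorder and present to varying degrees in nonclinical populations.
bodymapr implements the analysis core for two complementary digital
assessments of it:

* **2-D concern mapping.** Participants outline areas of appearance
  concern on a standard androgynous manikin (a fixed raster, so no
  spatial normalisation across bodies is needed), annotating each outline
  with concern types, emotions and an intensity rating. The analysis asks
  *where* two groups differ in how frequently they mark concern.
* **3-D size perception.** Participants set sliders for 13 body regions
  of an avatar to match their perceived body; seven of those regions have
  tape-measured counterparts. Slider units are converted to centimeters
  and compared with the actual measurements, giving a per-part
  *discrepancy score* (perceived − actual; negative = underestimation).

## 2-D model: proportional maps, z maps, permutation inference

Each subject's outlines are filled (even-odd rule on pixel centers;
scanline implementation) and OR-ed into one binary mask, so a subject
contributes at most once per pixel however many overlapping concerns they
drew. The group **proportional map** is the pixel-wise mean of these
masks. Group difference per pixel is the pooled two-proportion z,

z = (p1 − p2) / sqrt( p̄ (1 − p̄) (1/n1 + 1/n2) ),

with p̄ the pooled proportion; pixels where p̄ is 0 or 1 are degenerate
and carry z = 0. Significance is nonparametric: group labels are
randomly reassigned B times (group sizes preserved), and the two-sided
pixel p-value is the add-one estimator (1 + #{|z_b| ≥ |z_obs|})/(B + 1),
which is never smaller than 1/(B + 1) and remains valid for any B.

**Cluster-extent correction.** Supra-threshold pixels (p < α) are
grouped into 8-connected clusters. Every permuted map is thresholded by
the identical per-pixel rule, and the null distribution of the maximum
cluster extent supplies the critical extent (its 1 − α order statistic):
a cluster survives iff it is at least that large. This max-statistic
construction controls family-wise error at α over the whole raster.

Design choices the source procedure left open, and how they were fixed:

* *Sidedness*: two-sided via |z| — group effects run in both directions
  (each group has regions it marks more often).
* *Cluster-forming threshold*: the same α = 0.05 used for the final
  cluster-level test; exposed as a parameter.
* *Connectivity*: 8-connected, the common choice for 2-D pixel maps.
* *Smoothing order*: the description "cluster corrected and spatially
  smoothed" is ambiguous about order. Smoothing (Gaussian, FWHM 6 px,
  σ = FWHM/2.3548 ≈ 2.548 px) is applied to the per-subject masks before
  the z statistic — equivalently to the group proportion maps, since
  convolution is linear — and *identically inside every permutation*, so
  the permutation test remains exact either way. With smoothing the z
  formula uses effective counts x = n · (smoothed proportion).
* *Boundary handling*: reflective (mirror) padding avoids artificial
  attenuation at raster edges; the kernel is truncated at 4σ and
  renormalised (mass error < 1e-4), so constant maps are preserved and
  proportions stay in [0, 1].
* *Permutation sampling*: B relabelings drawn uniformly with replacement
  from the relabeling space; the observed labeling enters once through
  the add-one rule. One seed, recorded in the result object, makes every
  run reproducible.

## 3-D model: calibration and discrepancy

The avatar's parts were measured (in-engine) at slider 0, 0.5 and 1;
slider-to-cm conversion interpolates linearly on [0, 0.5] and [0.5, 1]
separately, continuous at the 0.5 baseline. The inverse mapping (used by
the synthetic generator) is exact on each segment. Discrepancy =
perceived − actual per part; the *scaled body average* is the mean over
the seven parts of measurement/reference. The reference is not defined
in the source description; we default to the calibration baseline (m05
per part), and expose it as a parameter, since a ratio near 1 for actual
bodies is what the published group values show. The published scaled
"difference" rows are on an inconsistent scale (≈ −0.6 against averages
≈ 0.98) and are deliberately not reproduced; we report the difference of
scaled averages.

Group comparisons of discrepancy profiles use one-way MANCOVA (Wilks'
Λ = det(E)/det(E + H), Rao's F; covariates entered before group, i.e.
the group effect is covariate-adjusted) with per-response post hoc
ANCOVA, partial η², Cohen f, and Benjamini–Hochberg adjustment. Welch t
(the printed fractional dfs imply unequal-variance t) and Pearson
chi-square reproduce the demographic tables from summary data alone.

## The synthetic world

No subject-level dataset is deposited, so the generator *is* the test
bed. Its defaults state the studied world once:

* group sizes 65 ("model") and 38 ("nonmodel"); raster 400 × 800 px
  (the manikin raster size is unpublished; tests use 64 × 128).
* two concern regions — thighs/buttocks (p = 0.74 vs 0.25) and abdomen
  (p = 0.20 vs 0.45) — matching the published endorsement counts for the
  first group in each case (48/65, 17/38); the cross rates are not
  published and were fixed once at plausible lower values. A Poisson(0.5)
  number of unstructured background concerns per subject brings mean
  concerns per subject to ≈ 1.2–1.4, matching the published range.
* concern intensity ~ Normal(30, 30) clipped to [0, 100] (published
  group means ≈ 27 and 38 with SDs ≈ 30); affect labels sampled with
  weights equal to the published pooled endorsement counts.
* actual part sizes ~ Normal with the published per-group means/SDs;
  perception bias = the published per-group discrepancy means; noise SD
  3 cm (published discrepancy SDs range ≈ 2.6–9).
* the calibration table is a **synthetic stand-in** (the scanned
  volunteer's in-engine measurements are unpublished): plausible female
  baselines at slider 0.5 with endpoints at 50%/150% of baseline, wide
  enough that realistic perceived sizes are representable. Perceived
  values outside the range are clipped *and counted* (`meta$n_clipped`);
  a bias that pushes every subject out of range aborts with advice to
  extend the calibration.

What a green test establishes — and what it does not: the generator
draws elliptical concern polygons with group-structured probabilities,
not human-shaped silhouettes or freehand outlines; sizes are Gaussian
and independent across parts, unlike real anthropometry; demographics
are sampled independently of concerns. Green therefore means the
*machinery* (rasterisation, smoothing, permutation calibration, effect
recovery, calibration inversion, table statistics) is correct under a
known truth, not that any scientific claim about real cohorts is
validated.

## Numerical choices and degenerate inputs

* Even-odd fill with half-open edge rule; pixel centers exactly on an
  outline are included. Vertices are continuous coordinates, 0-based,
  origin top-left.
* Degenerate polygons (< 3 vertices) and out-of-bounds vertices are
  errors, not warnings.
* All-agreeing pixels: z = 0, p = 1, never cluster.
* p-values are floored at 1/(B + 1) by construction.
* Permutation provenance (B, seed, α, smoothing) is stored in the fitted
  object; cluster correction refuses to run at a different α than the
  null was built at (the stored null extents would not apply).
* MANCOVA drops constant covariates (they carry no information; Λ is
  unchanged) and names collinear columns on rank deficiency.
* Printed-style percentages round half-up to 1 decimal, matching how
  such tables are typeset (R's default banker's rounding does not).

## Known limitations

* The cluster-forming threshold equals the final α by default; very
  diffuse effects may be better served by a lower forming threshold.
* Storage of the full permutation |z| matrix bounds B × raster size
  (a guard refuses > 4 GB); at the full 400 × 800 raster with B = 5000
  expect ≈ 1.3 GB per fit.
* The scaled-body-average reference is a modeling choice; comparisons
  across calibration tables require the same reference.
* Free-text affects default to "unclassified" valence and are excluded
  from valence tallies unless explicitly flagged negative; how the
  original instrument classified free text is unknown.
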