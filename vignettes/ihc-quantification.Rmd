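---
title: "Color-based IHC quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-based IHC quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The problem

Immunohistochemistry (IHC) renders an antibody-bound antigen brown (the DAB
chromogen) against a hematoxylin-blue nuclear counterstain. Pathologists
traditionally grade such slides on a discrete 1+ to 3+ scale; that is
semi-quantitative, coarse for heterogeneous tumors, and not scalable.
`ihcquant` implements a fully quantitative alternative built on color-based
pixel clustering, together with the cohort statistics needed to relate two
markers across patients (for instance cytoplasmic c-Cbl, an E3 ubiquitin
ligase, against nuclear beta-catenin, the readout of active Wnt signaling,
in colorectal cancer biopsies), and two small numeric utilities used
alongside such studies (protein half-life from translation-block
densitometry, and caliper-based xenograft tumor volume).

## The segmentation model

Every pipeline starts the same way:

1. **Color space.** The 8-bit sRGB image is converted to CIELAB (sRGB
   transfer function, D65 white point — the convention for brightfield
   camera output). L\* carries intensity; the (a\*, b\*) plane carries
   chromaticity. Working in (a\*, b\*) makes the stain classes nearly
   intensity-invariant: DAB brown has a\* and b\* both positive,
   hematoxylin has strongly negative b\*, eosinophilic/interstitial pink
   has positive a\* with near-zero b\*, and lumen is achromatic.
2. **Clustering.** Pixels are partitioned by k-means (k = 3) on their
   (a\*, b\*) coordinates: Lloyd's algorithm, squared Euclidean distance,
   k-means++ initialization, 10 restarts, SSE tolerance 1e-6, at most 300
   iterations. k = 3 reflects the three fundamental tissue compartments
   (cell-dense tumor, interstitium, lumen).
3. **Mode-specific readout:**
   - *Cytoplasmic marker* (`quantify_cytoplasmic_marker`): select the DAB
     cluster, remove connected components below `min_component_px`
     (default 5000 px), report the surviving pixel fraction.
   - *Nuclear marker* (`quantify_nuclear_marker`): re-cluster each
     first-tier cluster with k = 2 (`two_tier_cluster`), yielding six
     non-overlapping sub-masks; select the DAB-brown, nucleus-scale
     sub-masks and report the fraction of their union.
   - *Tumor area* (`quantify_tumor_area`): classify first-tier clusters by
     mean L\* and report the cell-dense (dark) area fraction.
   - *Positive nuclei* (`count_positive_nuclei`): nuclei are the
     nucleus-scale components of the hematoxylin-blue and DAB-brown
     sub-masks; a nucleus is positive when more than half its pixels are
     DAB; report `100 * positive / total`.

Marker fractions are finally **normalized to the tumor-area fraction** of
the same image (`normalize_to_tumor`), so images with little tissue do not
read as low expression. Images whose tumor fraction is zero are flagged and
excluded from cohort statistics.

## Mechanizing the expert-in-the-loop steps

In the original workflow a pathologist looks at the clusters and points at
the cytoplasmic one (or at the sub-images containing nuclear staining).
For reproducibility the package replaces that step with documented
chromaticity heuristics, while keeping the human overrides:

- **DAB score.** A cluster counts as DAB-brown when its centroid maximizes
  `s = a* + b*` (cytoplasmic mode) or its mean chromaticity satisfies
  `a* + b* >= dab_score_min` (default 20). Brown scores ~45 under typical
  staining; hematoxylin ~-19; backgrounds ~0-12, so the margin is wide. A
  winning score below the threshold flags the record `low_confidence`.
- **Hematoxylin test.** A sub-mask counts as blue-nuclear when its mean
  `b* <= blue_b_max` (default -32). True hematoxylin sits near b\* = -40;
  pale bluish-purple tissue rarely drops below about -28, so -32 separates
  counterstained nuclei from tissue background.
- **Nucleus scale.** A sub-mask is nucleus-scale when the pixel-weighted
  median of its connected-component sizes lies inside `nucleus_px_band`
  (default 5-2000 px). The pixel weighting matters: the second clustering
  tier often splits individual nuclei into two chromatic shades plus some
  single-pixel speckle, and an unweighted median collapses to that
  speckle, whereas a mask dominated by one large tissue blob still
  reports a very large weighted median and is correctly rejected.
- **Tumor-area selection.** The classic reading picks the single darkest
  cluster (lowest mean L\*) as tumor. That undercounts DAB-stained
  sections, where the tumor compartment (brown cytoplasm + blue nuclei +
  tissue base) legitimately spans two chromatic clusters. The default
  `"auto"` mode therefore takes the union of all clusters with mean
  L\* below `tumor_l_max` (default 75); `"darkest"` and `"fixed"` modes
  are available. If no cluster qualifies (e.g. an all-white image) the
  fraction is 0 and flagged.

All thresholds live in `ihc_config()` and every mode supports
`fixed`-index override and an `interactive` mode that writes per-cluster
preview PNGs and reads the chosen index back from a `choice` file.

## Numerical choices

- **Canonical labels.** After convergence clusters are relabeled by
  centroid (a\*, then b\*) ascending, so identical inputs give identical
  outputs and tests can refer to stable indices.
- **Restart policy.** For tiny point sets (at most 64 distinct k-subsets)
  the initialization enumerates every k-subset of points instead of
  sampling — deterministic, and in practice it attains the exhaustive
  optimum (verified against a brute-force bipartition oracle in the test
  suite). Images always use the k-means++ path.
- **Empty clusters** occurring during iteration are reseeded to the point
  farthest from its centroid, keeping k populated clusters; if all points
  are coincident (a uniform image) the surplus clusters are left empty
  instead of splitting identical points, and the six-mask contract of
  `two_tier_cluster` is preserved by emitting empty sub-masks.
- **Size filter boundary.** Removal is strict (`size < min_pixels`), so a
  component of exactly the threshold size survives. The default 5000 px
  corresponds to the acquisition scale the method was developed at and is
  magnification-dependent: tests on 256x256 synthetic scenes use 1250 px,
  the same threshold scaled by image area relative to 512x512.
- **Connectivity** defaults to 8-connected (standard for blob analysis);
  4-connected is a flag. Components are labeled in raster-scan order.
- **Dichotomization ties.** Patients exactly at a cohort mean are classed
  "low" (the split is strictly greater-than). Percentages are kept at
  full precision and additionally rendered half-away-from-zero to
  integers, matching how such tables are usually printed. Note that a
  published conditional of "83% (26 of 31)" is 83.87% unrounded — the
  package reports 83.87 and renders 84.
- **Spearman p-values** use the exact permutation distribution for
  n <= 10 without ties and the t approximation otherwise; the rank-sum
  test enumerates exactly when both groups have at most 8 untied values
  and uses the tie-corrected normal approximation otherwise.
- **Half-life interpolation** between the two samples bracketing 50% is
  linear in log(fraction) — first-order decay is the canonical model for
  protein loss after a translation block, and this makes the estimator
  exact on any sampled exponential. Plain linear interpolation is a flag.
  When the series never reaches 50%, a log-linear regression over all
  points is extrapolated and the estimate is flagged.
- **Tumor volume** is `V = l * w^2 / 2`, the standard caliper ellipsoid
  formula (`l` = longer axis). A literal product `l * w` is available
  behind `literal = TRUE` for auditing against legacy records.

## The synthetic-data generators

No imaging cohort is bundled; instead three generators produce inputs with
exact ground truth, and they define the conditions under which the test
suite and the acceptance checks run.

**Images** (`generate_ihc_image`). Compartment geometry comes from smooth
Gaussian-bump random fields thresholded at the exact pixel count for the
requested coverage, so regions are large contiguous blobs and the
ground-truth fractions are exact by construction. Inside the tumor, DAB
cytoplasm patches are carved from a second field and nuclei are
non-overlapping ellipses (semi-major axis 3.5-6 px) placed fully inside
the tumor, a seeded subset rendered DAB-positive. Default stain colors
(DAB RGB (120,70,40); hematoxylin (60,60,130); interstitium (240,205,218);
lumen (245,245,245); tissue base (140,130,185)) were chosen once so that
the four stain classes are well separated on the (a\*, b\*) plane and the
cheap k = 3 merges are stable (pale classes together, dark blue-purple
classes together, brown alone). Gaussian pixel noise (SD 4 of 255) is
added and the result is re-quantized to 8 bits. What the generator does
*not* emulate: stain intensity gradients, chromatic mixing at edges
(antialiasing), out-of-focus blur, tissue folds, and hematoxylin-DAB
co-localization within a nucleus. Passing tests therefore demonstrate that
the pipeline recovers known areas under idealized but noisy color
statistics — not performance on real slides, which is why the expert
override modes exist.

**Cohorts** (`generate_cohort`). Patient-level marker pairs come from a
bivariate Gaussian copula with Pearson parameter `r = 2 sin(pi * rho_s / 6)`,
the exact inverse of the Spearman correlation of a bivariate normal, so
the latent rank correlation equals the target (default -0.64, n = 83).
Latents map to lognormal scales (location log 0.05 / log 0.30, scale
0.8 / 0.6 for the nuclear and cytoplasmic marker respectively) —
strictly nonnegative and right-skewed like tumor-normalized pixel
fractions. Each of the (default) 5 images per patient multiplies the
patient value by lognormal within-patient noise (log-SD 0.25),
representing intra-tumor heterogeneity. Averaging 5 noisy images
attenuates the recovered patient-level correlation slightly: a 1000-seed
Monte-Carlo run of the generator gives a mean recovered rho of about
-0.61 with central 95% interval [-0.745, -0.472], which is the band the
acceptance suite checks against. A consequence of this hierarchical model
is that the image-level correlation is always weaker than the
patient-level one; a dataset in which the image-level association is the
stronger of the two cannot be produced by this generator.

**Decay series** (`generate_decay_series`) draw
`marker(t) = A 2^(-t/t_half) e^eps` with a constant loading control, both
under lognormal noise; at `noise_sd = 0` the normalized series is the
exact exponential. The default chase timepoints are
{0, 15, 30, 60, 120} min.

All generators are pure functions of their parameters and seed.

## Problem sizes used by the tests

The test and acceptance suites run on 256x256 (occasionally 96-128 px)
scenes with the area-scaled 1250 px size filter, 20-image accuracy
batches, 100-seed Monte-Carlo loops for the half-life estimator, and
100 random small instances for the k-means optimality check; these sizes
were chosen as the smallest at which each property is meaningfully
exercised. The two-tier structural check runs at the default image size;
the cohort checks use the full 83-patient design.

## Known limitations

- Chromaticity heuristics assume standard DAB/hematoxylin staining;
  unusual chromogens need re-configured thresholds or fixed indices.
- Nuclei counting assumes mostly non-touching nuclei; merged clumps count
  once. Components are not split by watershed or shape analysis.
- Images in which cytoplasmic DAB and nuclear DAB coexist cannot be
  decomposed by color alone: nuclear quantification is intended for
  sections whose DAB signal is nuclear, cytoplasmic quantification for
  the converse, matching how consecutive slides are stained in practice.
- No whole-slide (pyramidal) support and no stain-vector color
  deconvolution; the method is clustering-based by design.
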