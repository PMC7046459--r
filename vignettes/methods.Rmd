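---
title: "Quantifying amyloid plaque morphology and its microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaque morphology and its microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periplaque)
```

# The problem

In mouse models of β-amyloidosis, the biology of interest is not only how
much plaque accumulates but what form it takes and what happens in the
tissue immediately around each deposit. Microglia normally compact
fibrillar Aβ into dense cores; when microglial function is impaired (for
example by *Trem2* deletion), plaques become more diffuse, dystrophic
neurites (Lamp1⁺ axonal swellings) expand around them, and ApoE
accumulates on the plaque surface. Turning stained sections into numbers
therefore needs several bespoke measurements beyond generic blob counting:
per-plaque microenvironment territories, a morphological compaction index,
colocalization within microglia, and module-level expression scores from
sorted microglia. `periplaque` implements that chain as reusable,
synthetic-data-testable components.

# Segmentation of stained structures

Fluorescent channels (methoxy-X04/X-34 for fibrillar plaque, Iba1 for
microglia, Lamp1 for dystrophic neurites, ApoE) are segmented by:

1. a **white top-hat** with a disc structuring element (default radius
   25 µm) that removes slowly varying background while preserving objects
   smaller than the disc;
2. a **local mean threshold**: a pixel is foreground when its top-hat
   value strictly exceeds the mean over a square window (default 75 µm)
   plus an additive offset (default 0);
3. binary **opening then closing** with a 1-pixel disc;
4. **8-connected component labelling** and a minimum-size exclusion,
   34 µm² for the costained channels and 9 µm² for X-34, converted to
   pixels conservatively as `ceiling(min_size / pixel_area)`;
5. optional **shape filtering** (below) for the Lamp1 and methoxy-X04
   channels, where elongated staining artefacts (vessels, processes) must
   not be counted as plaques or neuritic blobs.

The local mean is computed exactly with a summed-area table, with windows
clipped at the frame edge. The strict `>` comparison means a perfectly
flat region is never foreground, so blank images yield zero objects
rather than noise. The offset deserves a note: a local *mean* threshold
with zero offset admits, by symmetry, about half of all background noise
pixels before morphology cleans them up, and on large noisy frames a rare
noise cluster can survive the opening and the size filter. When the
background noise level is known or estimable, we set the offset to about
twice the noise SD; the worked analyses on synthetic scenes (noise SD 5)
use offset 10. The neutral default remains 0 because the offset is in
intensity units and no universal value is meaningful across stains.

## Shape features

Three dimensionless descriptors are computed per object, each in (0, 1]
for ideal shapes and approaching 1 for a disc:

* **shape factor** `4πA/P²` (circularity),
* **roundness** `4A/(πL²)` where `L` is the ellipse-equivalent major axis
  length from second-order moments,
* **solidity** `A / A_hull`, the area over its convex hull's.

Rasterization details matter here. The perimeter comes from a
Vossepoel–Smeulders weighted chain code on the traced boundary; since the
chain passes through boundary-pixel centres — half a pixel inside the true
outline — we add the `π` that a half-pixel outward offset of a convex
outline contributes. The hull is taken over pixel centres augmented with
pixel corners so that solidity cannot blow past 1 for small objects.
Values may still exceed 1 by a few percent for coarse rasterizations and
are capped at 1.25; objects of one or two pixels get all features set
to 1 by convention (a point is round). Default lower bounds, applied only
where shape filtering is requested, are solidity ≥ 0.5 and roundness
≥ 0.2; a 1-pixel-wide bar of 30 px has roundness ≈ 0.03 and is removed,
while an equal-area disc scores ≈ 0.98 and survives. These bounds are
configuration values echoed into every output, not hidden constants.

## Colour classification of brightfield stains

Silver and IHC stains are segmented by combinations of narrow inclusive
ranges in RGB and/or HSV space (H in [0,360), S,V in [0,1]), each tagged
positive or negative; a pixel is positive when inside at least one
positive box and no negative box. Cleanup (opening/closing, minimum size)
is configurable. This mirrors interactive colour-classifier workflows on
whole-slide scanners.

# Peri-plaque microenvironment

Detected plaques seed a **marker-controlled watershed**: every pixel joins
the influence zone of its nearest plaque under the Euclidean distance
transform (the standard surface for marker-controlled watershed when only
markers are given; its catchment basins are exactly the geodesic influence
zones). Pixels whose two smallest plaque distances tie exactly are
watershed lines and belong to no zone. Each plaque mask is then dilated by
17 µm but **constrained to its own zone**, which prevents the rings of
plaques closer than 34 µm from merging; ring sets of distinct plaques are
disjoint by construction, and every ring pixel is within 17 µm of its own
plaque.

Marker fractions then follow two normalizations:

* **ring-normalized** (Lamp1, Iba1): signal ∩ ring / ring area, in [0, 1];
* **plaque-normalized** (ApoE): signal ∩ (plaque ∪ ring) / plaque area,
  which may exceed 1 since the search region is larger than the
  denominator.

The ring-normalized reading excludes the plaque interior from both the
numerator's search region and the denominator; the phrase "dilated area
around plaque" is ambiguous on this point, so the choice is recorded in
the output metadata. Section-level values use the pooled-pixel ratio
(total signal over total territory) rather than a mean of per-plaque
fractions, which would overweight small plaques; per-plaque values remain
available. Whole-section statistics are percent positive area over a
tissue mask obtained by thresholding the Iba1 channel (Otsu by default)
followed by closing and hole filling. Animals aggregate as unweighted
means over their sections.

# Plaque diffuseness

X-34 confocal stacks (eleven slices at 1 µm) are maximum-projected, and an
initial segmentation mask is taken at the intensity exceeding 99.99% of
all pooled pixels of control images without positive staining (strict
`>`), then smoothed (1-pixel opening/closing) and purged of objects under
9 µm². Two further global thresholds — the 80th and 50th percentile of the
pixels inside the segmentation masks of *all* positive images of the
batch, pooled — define the compact and compact+diffuse masks. The
per-image **diffuseness index** is

$$ \mathrm{DI} \;=\; \frac{A_{\text{diffuse+compact}} - A_{\text{compact}}}
       {A_{\text{diffuse+compact}}} \in [0, 1], $$

0 for a fully compact plaque and approaching 1 as the halo dominates.
Percentiles use linear interpolation between order statistics throughout
(the common default, and checkable against a sort-based oracle);
percentile masks threshold inclusively (`≥`) within each image's own
positive mask, so the 0th percentile reproduces the input mask. Because
both thresholds scale linearly with the data, the index is invariant to a
global intensity rescaling and to the order of images within a batch. The
batch — the unit across which percentile pooling happens — should be one
cohort stained and imaged together; it is a grouping key in
`run_diffuseness()`, and per-batch recomputation is the implemented
behaviour.

A useful validation property of the piecewise-constant synthetic plaques
(core plateau over halo plateau): when the core plateau holds between 20%
and 50% of plaque pixels, the pooled 80th percentile necessarily lands on
the core plateau and the 50th on the halo, so the recovered index equals
`1 − (r_core/r_halo)²` up to rasterization. Outside that window the
percentile pair no longer isolates the plateaus — which is a property of
the dual-percentile method itself, not of the implementation — so the
validation scenes keep core fractions inside it.

# Colocalization

Thresholded Mander's coefficients are computed over every voxel of the
full z-stack, never on projections: M1 is the fraction of channel A's
supra-threshold intensity lying in voxels where B also exceeds its
threshold, and M2 the converse. Thresholds are fixed per channel across
samples and logged; comparisons are strict, so an empty channel yields a
missing value rather than a fabricated coefficient. No automatic (Costes)
threshold selection is attempted.

# Gene-module scoring

Expression arrives as a genes × samples matrix of nRPKM-scale values. For
display-style z-scoring, matrices are transformed as `max(log2(nRPKM),
−4)` and each gene centred and scaled (sample SD, n−1 denominator;
zero-variance genes map to all-zero rows). The **gene set score** of a
sample is the mean over set genes of that sample's log2 value minus the
gene's mean log2 value across samples, so scores of a set always sum to
zero across samples. Genes with zeros in some samples receive an imputed
log2 value one log2 step below the lowest detected value of that gene;
genes detected nowhere are dropped from the set with a message. The floor
is *not* applied before scoring by default — the −4 floor belongs to the
heat-map transform, which is a separate procedure — but a `floor` argument
restores it for sensitivity analyses. Group comparisons use two-tailed
Welch tests (unequal variances, Welch–Satterthwaite df); no multiple-test
correction is applied across sets by default, with Benjamini–Hochberg
available as an option.

# The synthetic-data generator

`make_scene()` renders plaques as a bright core disc (intensity 200) on a
dimmer halo annulus (100) over background (10), with additive Gaussian
noise (SD 5) clipped at zero — a core SNR of 38, typical of well-exposed
whole-slide scans. The piecewise-constant radial profile is deliberate:
it makes the true compact and total areas exactly `πr²`, so the
diffuseness chain can be validated analytically rather than against
another estimator. Default geometry is core radius 8 µm and halo radius
14 µm at 1 µm/pixel. Plaque centres are rejection-sampled with a minimum
separation of `2·(halo + 2 µm)` (cores may never overlap; the default
keeps whole plaques separable, matching the watershed use case) and a
bounded retry budget that fails with an explicit density error. Lamp1 is
rendered as small blobs near plaque rims, Iba1 as soma discs with thin
processes pointing at the plaque over a diffuse parenchymal baseline, and
ApoE as puncta; each channel has a rasterized true mask in the truth
record. `make_expression()` draws per-gene log2 baselines (mean 4, SD 1),
adds planted log2 effects to module genes in the second group and iid
noise (SD 0.5), exponentiates, and applies dropout zeros (default 10%) at
the nRPKM scale so the imputation rule is genuinely exercised. Group
sizes default to 7 vs 7, the scale of a sorted-microglia cohort.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: optical blur and point-spread functions,
intensity falloff with depth, autofluorescence texture, irregular plaque
shapes, spatially correlated noise, library-size artefacts, and
count-based mean–variance structure in expression. The tests certify the
*operators* (thresholds, morphology, geometry, scores) against ground
truth, not the biological validity of any particular parameter setting.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics everywhere.
* Strict `>` for control-background and Mander's thresholds; inclusive
  `≥` for the within-mask percentile masks (so the lower bound keeps its
  own mask).
* Size filters: pixel threshold `ceiling(min_size/pixel_area)`,
  conservative in the exclusion direction.
* Connectivity: 8-connected in 2D, 26-connected in 3D.
* Watershed ties (exact distance ties) become line pixels with label 0.
* Blank images segment to empty label maps, not errors; an empty tissue
  mask or an empty pooled percentile pool is an error, because a
  normalization would be undefined.
* All randomness flows through explicit integer seeds in the generator
  specs; reruns of any pipeline entry point with identical inputs and
  configuration are byte-identical.

Validation problem sizes are kept modest — scenes of 128–320 µm at
1 µm/pixel, 50-scene property sweeps, 100-replicate recovery simulations —
which is ample for the contracts being checked while keeping the whole
suite fast.

# Limitations

Stitching, illumination correction and machine-learned segmentation are
out of scope; the colour classifier is a box model, not a trained
classifier; the watershed surface is purely geometric (distance), not
intensity-weighted; and differential expression, nRPKM computation from
raw reads and gene-ontology analyses are intentionally not reimplemented
here — established tools already do those well.
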