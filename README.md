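# periplaque

Quantitative analysis of β-amyloid plaque pathology and its cellular
microenvironment, for researchers working with mouse amyloidosis models
(PS2APP, 5xFAD, APP/PS1 and similar), plus gene-module scoring of
sorted-microglia expression profiles. The package turns stained-section
micrographs and confocal z-stacks into per-plaque, per-section and
per-animal measurements, and ships a ground-truthed synthetic-data
generator so every stage is testable without any imaging data.

## What it computes

**Segmentation.** Fluorescent channels (methoxy-X04/X-34, Iba1, Lamp1,
ApoE) are segmented by a white top-hat filter, a local mean threshold,
binary opening/closing, 8-connected labelling, minimum-size exclusion
(34 µm² costain / 9 µm² X-34) and shape filtering (shape factor 4πA/P²,
roundness 4A/(πL²), solidity A/A_hull) to remove elongated artefacts.
Brightfield silver/IHC stains are segmented by positive/negative colour
classifiers in RGB/HSV space.

**Peri-plaque microenvironment.** Detected plaques seed a
marker-controlled watershed on the Euclidean distance transform; each
plaque mask is dilated by 17 µm constrained to its own influence zone, so
rings of nearby plaques never merge. Marker signal is then quantified as

- ring-normalized fractions (Lamp1, Iba1): `area(signal ∩ ring) / area(ring)`,
- plaque-normalized fractions (ApoE): `area(signal ∩ (plaque ∪ ring)) / area(plaque)`,

plus whole-section percent positive area over an Iba1-derived tissue mask.

**Plaque diffuseness.** X-34 maximum projections are masked at the
intensity exceeding 99.99% of pooled control-image pixels; the 80th and
50th percentile of in-mask pixels pooled over the batch define compact and
compact+diffuse masks, and

```
DI = (Area_diffuse+compact − Area_compact) / Area_diffuse+compact
```

is 0 for a fully compact plaque and approaches 1 as the halo dominates.

**Colocalization.** Thresholded Mander's coefficients M1/M2 over entire
z-stacks with fixed per-channel thresholds.

**Gene modules.** `max(log2(nRPKM), −4)` transforms, per-gene z-scores, and
per-sample gene set scores (mean gene-wise deviation of log2 expression
from the across-sample gene mean, with undetected values imputed one log2
step below the gene's lowest detected value), compared between genotype
groups by two-tailed Welch t tests.

## Worked example

```r
library(periplaque)

# a ground-truthed synthetic field: 6 plaques (core r = 8 um, halo r = 14 um)
sc  <- make_scene(scene_spec(n_plaques = 6, width_um = 220, height_um = 220,
                             seed = 42))
seg <- segment_fluorescence(sc$channels$X04, local_offset = 10,
                            min_size_um2 = 34,
                            shape_limits = list(solidity = 0.5, roundness = 0.2))
seg
#> Segmentation: 6 objects, 1 um/px
head(seg$table[, c("label", "area_um2", "shape_factor", "roundness", "solidity")], 3)
#>   label area_um2 shape_factor roundness  solidity
#> 1     1      618    0.9947423 0.9917296 0.9566563
#> 2     2      619    0.9922600 0.9903956 0.9559846
#> 3     3      616    0.9959819 0.9971163 0.9602494
```

All 6 plaques are recovered; areas sit within ~1% of the analytic truth
π·14² ≈ 615.8 µm², and near-1 shape features confirm round objects. Next,
the 17 µm constrained dilation and the Lamp1 microenvironment fraction:

```r
rings <- constrained_dilation(seg$labels, radius_um = 17)
lam   <- segment_fluorescence(sc$channels$Lamp1, local_offset = 10,
                              min_size_um2 = 9)
paf <- plaque_associated_fraction(binary_mask(lam$labels$data > 0, 1),
                                  seg$labels, rings, mode = "ring")
head(paf[, c("plaque_id", "plaque_area_um2", "ring_area_um2", "fraction")], 3)
#>   plaque_id plaque_area_um2 ring_area_um2   fraction
#> 1         1             618          2368 0.02111486
#> 2         2             619          1857 0.02907916
#> 3         3             616          1511 0.02978160
attr(paf, "section_fraction")   # pooled-pixel section-level value
#> [1] 0.0247
```

Each plaque's ring is its 17 µm neighbourhood clipped by the watershed
lines; 2–3% of that territory carries Lamp1 signal in this synthetic
field. The diffuseness chain recovers the analytic index of two-plateau
plaques, `1 − (8/14)² = 0.6735`:

```r
ctrl <- list(image_grid(matrix(10, 50, 50), 1))   # background-only control
imgs <- lapply(1:3, function(s)
  make_scene(scene_spec(n_plaques = 4, width_um = 200, height_um = 200,
                        noise_sd = 0, seed = s, channels = "X04"))$channels$X04)
diffuseness_pipeline(imgs, ctrl)$per_image
#>      image area_compact_um2 area_dc_um2     index
#> 1 image_01              808        2457 0.6711437
#> 2 image_02              791        2445 0.6764826
#> 3 image_03              798        2458 0.6753458
```

And a planted +1.5 log2 effect on a 50-gene module in 7-vs-7 samples is
flagged by the Welch comparison:

```r
ex <- make_expression(expr_spec(n_genes = 300, n_samples_per_group = 7,
                                modules = list(DAM = sprintf("g%04d", 1:50)),
                                effects = c(DAM = 1.5), seed = 7))
run_modules(quant_config(), matrix = ex$matrix, groups = ex$groups,
            sets = list(DAM = sprintf("g%04d", 1:50)))$comparisons
#>   gene_set     mean_a    mean_b         t            p
#> 1      DAM -0.7302391 0.7302391 -18.18199 4.655676e-08
```

The group score means of ∓0.73 differ by ≈ 1.5 log2 units, the planted
effect (scores of a set always sum to zero across samples, so a
symmetric two-group effect splits evenly around 0).

Batch entry points `run_costain()`, `run_diffuseness()` and
`run_modules()` orchestrate cohorts (animal → section → field) from
manifest data frames and write per-plaque/per-section/per-animal CSVs with
the full configuration echoed in each header. A thin command-line wrapper
with the same functionality lives at `inst/cli/periplaque.R`
(subcommands `simulate-scene`, `simulate-expression`, `segment`,
`costain`, `diffuseness`, `coloc`, `modules`).

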