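---
title: "ECM structure metrics and the structure index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECM structure metrics and the structure index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecmtme)
```

This vignette is the package's account of its methods: what each stage
computes, the assumptions behind it, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the problem was genuinely open.

## The scientific setting

In chemotherapy-responsive tumors, treatment remodels the fibrous
extracellular matrix: high-density matrix and fiber curvature fall,
inter-fiber gaps and lacunarity rise. These structural changes travel
with an immunological shift that can be read from bulk transcriptomes as
an **anti-TME score** — the per-sample enrichment of the union of M1
macrophage, Th1, anti-tumor-cytokine and B-cell signature genes. The
package's central construct, the **structure index**, condenses the ECM
metric panel into one number per sample oriented so that "architecture
associated with a good response" scores high, and then asks which
matrisome genes track that index in a responsive model but not in a
poorly responsive one — nominating them as candidate targets for
matrix-directed co-treatment.

## Image stage

**Stain separation.** Brightfield RGB images are converted to optical
density, `OD = -log10((I + 1) / 256)` per channel, and unmixed against a
stain basis (H-DAB to isolate brown chromogen staining of matrix
proteins, H-PAS to isolate the blue collagen component of trichrome
stains; custom 3×3 bases accepted). The third basis vector is the
normalized cross product of the two stains. The returned gray image maps
OD linearly onto [0, 255] with 255 at the maximum representable
single-channel OD (`log10 256`), so denser staining is brighter; this
keeps the high-density-matrix threshold semantics intuitive.

**Skeleton and counts.** The fiber mask (supplied, or obtained by Otsu /
fixed thresholding) is thinned with the Zhang–Suen two-subiteration
algorithm and traced into a graph: pixels of 8-neighborhood degree 1 are
endpoints, degree ≥ 3 are branch pixels (adjacent branch pixels merge
into one branchpoint), and ordered pixel paths connect them, with step
length 1 for axial and √2 for diagonal moves. Connected skeleton
components without any node pixel become single closed-loop edges.
Branch and endpoint counts are normalized by total length; average fiber
length is total length over the edge count. Two conventions worth
knowing: (i) traced edges stop at the first branch pixel of a junction
cluster, so total length slightly undercounts the few pixels interior to
junction clusters; (ii) Zhang–Suen thinning is not exactly equivariant
under 90° rotation on thick masks — counts and lengths can shift by
roughly a percent. On already-thin (1 px) structures thinning is a no-op
and counts and lengths are exactly rotation-invariant; the test suite
checks exact equivariance there and 2% agreement for the continuous
metrics.

**Curvature.** Each edge path is resampled by linear interpolation at a
fixed arc spacing (the window, 10–40 px); the metric is the mean
absolute angle between successive chords, in degrees, pooled over all
edges at least twice the window long. With no eligible edge the value is
undefined (`NA`), never 0. For a circle of radius r the expected chord
turn is `2 asin(w / 2r)`; digitization inflates the measured arc length
of oblique paths by a few percent, which biases the measured turn
angle low by about the same amount — within the 10% tolerance used in
the tests. For a driftless random walk with per-step turning SD σ the
expected turn per w-px chord is about `σ √w`, which the generator tests
confirm.

**Gaps.** Gaps are greedy maximal inscribed circles in the background:
from the Euclidean distance transform of the background, repeatedly take
the global maximum radius r, record area πr², zero the transform on that
disk, and stop when r falls below `min_gap_radius_px` (default 2). This
is deliberately simple and deterministic; for non-circular holes it
tiles the hole with several circles (the largest circle of each hole
still dominates), which is the behavior the tests pin down.

**Lacunarity and fractal dimension.** Gliding-box lacunarity
`Λ(r) = E[m²]/E[m]²` over all positions of an r×r box, summarized as the
mean over dyadic r up to a quarter of the short image side (per-size
values are also returned). Box-counting fractal dimension is the
least-squares slope of `log N(ε)` against `log(1/ε)` over dyadic box
grids anchored at the image origin; anchored grids keep the Sierpinski
and filled-square oracles exact, at the price of mild sensitivity to
pattern placement (about 3% across rotations on non-dyadic canvases).

**HDM and thickness.** HDM is the fraction of pixels at or above a
saturation threshold (default 140/255, exposed in
`metrics_config()` — published workflows expose this as a tunable and no
single value is canonical). Fiber thickness is derived as
`HDM × image area / total skeleton length`. When only a mask is
available, HDM falls back to the mask's foreground fraction, which makes
the thickness formula measure the drawn fiber width (a 3-px bar measures
3.1 px).

## Texture stage

Intensities are quantized into 16 equal-width bins over the (masked)
min–max range; co-occurrence counts at offsets (0,1), (1,0), (1,1),
(1,−1) are symmetrized, normalized, and summarized as contrast, energy,
homogeneity, entropy (base-2) and marginal correlation, averaged over
the four directions. Min–max quantization makes contrast invariant to
constant intensity shifts. Because staining intensity drifts between
experiments, features measured across batches are normalized by the
**ratio of control medians**: each batch's values are multiplied by
`median(reference controls) / median(batch controls)`, which makes every
batch's control median exactly equal to the reference's — the estimand
the tests assert. Batches without control samples are an error, not a
silent skip.

## Expression stage

Counts are filtered by detection — a gene is kept when its cpm reaches 1
in at least 25% of samples, inclusively, so 1 of 4 samples suffices —
then transformed to `log2(RPKM + 1)`. The per-sample scorer is the
ssGSEA running-sum statistic: genes ranked by descending expression
(ties broken by gene identifier, making scores fully deterministic),
in-set increments weighted by `rank^0.25` and normalized, out-of-set
increments uniform, score = mean running difference. It is invariant
under monotone transforms of the expression column. The widely used
alternative (GSVA's KCDF statistic) ranks samples nearly identically in
the regimes exercised here; the running-sum form was chosen because it
can be verified against hand enumeration, and the choice is surfaced in
the documentation. The anti-TME score is the same statistic on the exact
union of the four member signatures (duplicates counted once). Shipping
signature files are synthetic placeholders with the right structure
(`inst/extdata/synthetic_anti_tme.gmt`); real analyses should supply
curated GMTs, with orthologue mapping handled upstream as a two-column
table.

Gene clustering is plain Euclidean K-means on row-z-scored profiles
(k = 7 by default, 25 restarts, deterministic given a seed); gene-set
overlaps use the exact hypergeometric upper tail.

## Integration stage

Spearman correlations drop incomplete pairs and refuse constant vectors
(`NA` with a reason, never 0). Without ties the p-value comes from the
exact permutation distribution of the rank statistic (exact enumeration
at small n, the standard AS 89 approximation of that distribution
otherwise); the t-approximation is used only when ties force it. The
exact form matters: at the study's n = 15 the t-approximation rejects a
true null 5.3% of the time versus 4.9% for the exact distribution, and
the target screen's specificity condition is exactly such a null event.

The metric screen classifies each metric as positive (r ≥ 0.5 and
p ≤ 0.05), negative (r ≤ −0.5, p ≤ 0.05) or neither; no multiple-testing
correction is applied by default (the screen uses a raw-p-with-r-floor
rule; a BH option exists). "Scaling" the selected metrics is per-metric
min–max to [0, 1] across samples — chosen over z-scoring (available via
a switch) because it matches the radar-plot convention of scaling group
means to the observed range, and because it makes the index invariant to
affine rescaling of any raw metric. The index is the ratio of the means
of the scaled positive and negative sets, with δ = 0.1 added to both
numerator and denominator so a sample that scales to 0 on every negative
metric keeps a finite index; means (not sums) are used so that unequal
set sizes do not introduce a constant factor. Swapping the sets maps
`(a + δ)/(b + δ)` to `(b + δ)/(a + δ)` exactly. The screen pools treated
and control samples across all timepoints of the responsive model;
per-timepoint screens are possible but not the default.

Target ranking computes, per gene, the Spearman correlation with the
index in each model; a candidate must be strong and significant in
model A (|r| ≥ 0.5, p ≤ 0.05) and non-significant in model B
(p > 0.05). Both directions are reported with their sign, since both
positively and negatively index-associated regulators are biologically
actionable. Note the structural consequence of the specificity
condition: even for a perfectly recovered model-A association, the
probability of candidacy is capped by P(p\_B > 0.05) ≈ 0.95 under the
model-B null, so recovery power for planted targets hovers at ~95% by
construction.

## Spatial stage

Phenotypes are gated in a fixed first-match-wins order — CD8 T cell
(CD8+), B cell (B220+), TAM (CD206+ or F4/80+ or CD163+, and aSMA−),
CAF (aSMA+ or S100A4+, and CK14−, CK19−, F4/80−), else "other". The
order resolves double-positive cells (a CD206+ aSMA+ cell fails the TAM
gate and lands in CAF when its cytokeratins and F4/80 are negative); it
is configurable because no single resolution is canonical. The gates are
mutually exclusive and exhaustive, property-tested over all 2¹² marker
combinations.

Distances to the tumor interface are read off a rasterized Euclidean
distance transform at the region's calibration (1 µm/px by default):
positive outside the region, zero on tumor edge pixels, negative inside.
Profiles bin |distance| into `n_bands` bands of `band_width_um` on one
side of the interface (default inside the tumor, 25 × 20 µm = 500 µm;
the 40 µm × 12 preset reproduces coarser zone analyses — both
conventions appear in practice and neither is asserted as the right
one). Band areas come from the same distance grid restricted to the
tissue mask, so banded counts are conserved exactly and densities are
counts over areas.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults were fixed once and are not tuned to test
outcomes.

* **Fiber images**: fibers are biased random walks (per-step Gaussian
  turning angle with SD `curvature_param`), dilated to the requested
  thickness via the distance transform (raster dilation of a 1-px line
  yields odd effective widths), composed into bright-on-dark gray
  images with Gaussian noise (SD 8 on a 195-level separation, so the
  mask is reproduced exactly by thresholding). They emulate fiber
  number, curvature, thickness and gap structure — not the chromogen
  appearance, nonuniform illumination, or out-of-focus blur of real
  H-DAB slides, so passing image tests demonstrates metric correctness,
  not robustness to staining artifacts.
* **Cohorts**: two models × two arms × three timepoints. A latent
  per-sample driver z ~ N(0, 1) carries the anti-TME state;
  `signature_effect` shifts it in treated model-A samples, signature
  genes track it with coupling 1 on the log2 scale over a baseline
  `U(3, 8)` with noise SD 0.5 (log2-scale biological plus technical
  noise typical of bulk RNA-seq at this depth). Planted metric–driver
  and target–driver Spearman correlations are imposed through a
  Gaussian copula on rank-normal scores (`ρ_P = 2 sin(πρ_S/6)`), which
  survives the generator's monotone output transform; tumor weight is a
  decreasing function of the driver. With all effects at 0 the arms are
  exchangeable. Real metric distributions are unknown — no public
  per-tumor metric tables exist — so the synthetic scales are arbitrary
  by construction and only rank-based statements transfer.
* **Cell maps**: cells are placed with intensity linear in distance
  from the tumor boundary (clipped at zero), `gradient = 0` giving a
  homogeneous pattern, and receive the canonical marker pattern of a
  phenotype drawn from the requested mix, so the gates recover the mix
  exactly.

All randomness flows from one integer seed through per-component
derived seeds; no generator touches the caller's RNG state, and
identical ground truth reproduces outputs bit-identically.

## Validation scales

The test suite and `scripts/acceptance.R` use problem sizes chosen to
make every Monte-Carlo estimate stable at desk scale: cohorts of 15
samples per model (100 replicates) for recovery, 40 per model
(200 replicates) for null calibration of the metric screen, 5 000 cells
for the spatial uniformity test, and 128–256 px canvases for the
geometry oracles. Recovery under these conditions: planted ±0.9 metric
sets recovered in ≥ 99% of replicates, index–driver Spearman r ≈ 0.97
(median), null metric selection ≪ 1%, null target candidacy ≈ 4.6%, and
planted-target candidacy ~95% — at the structural ceiling discussed
above.

## Known limitations

* Junction-cluster undercounting and thinning anisotropy (above) make
  skeleton lengths approximate at the percent level on thick masks.
* Curvature on dense fiber webs fragments into short edges; windows
  longer than typical edge lengths return `NA` rather than a biased
  estimate.
* The gap finder's greedy circles are a model of "gaps", not a
  segmentation; non-circular gaps are tiled.
* The cpm filter is not exchangeable with sample subsetting (documented
  and tested as an inequality) — filter on the full cohort first.
* Rasterized interface distances quantize at the pixel scale; at
  1 µm/px this is negligible against 20 µm bands.
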