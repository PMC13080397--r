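# ecmtme

Quantitative integration of extracellular-matrix (ECM) architecture with
tumor-microenvironment transcriptomics, for studies asking whether the
structure of the fibrous matrix — not just the amount of it — marks
response to chemotherapy in high-grade serous ovarian cancer (HGSOC)
models and similar settings.

The package covers five analysis stages, each usable on its own:

1. **ECM structure metrics** from stained-tissue images: color
   deconvolution of H-DAB / H-PAS stains via the optical-density model,
   skeletonization of the fiber mask into a centerline network, and the
   metric panel — total fiber length, branch/endpoint counts (normalized
   by total length), average fiber length, curvature at 10–40 px chord
   windows, high-density matrix fraction (HDM), mean gap area (maximal
   inscribed background circles), gliding-box lacunarity
   Λ(r) = E[m²]/E[m]², box-counting fractal dimension, and the derived
   fiber thickness = HDM × image area / total length.
2. **Haralick texture** (contrast, correlation, energy, homogeneity,
   entropy) from gray-level co-occurrence matrices, with
   ratio-of-control-medians batch normalization across staining
   experiments.
3. **Per-sample signature scoring**: cpm detection filtering, log2 RPKM,
   an ssGSEA-style running-sum enrichment score, and the composite
   **anti-TME score** — the enrichment of the union of M1, Th1,
   anti-tumor-cytokine and B-cell signature genes.
4. **The structure index**: ECM metrics are screened by Spearman
   correlation against the anti-TME score (|r| ≥ 0.5, p ≤ 0.05); each
   selected metric is min–max scaled to [0, 1] across samples, and the
   per-sample index is
   `(mean scaled positively-correlated metrics + δ) / (mean scaled
   negatively-correlated metrics + δ)` (δ = 0.1). Matrisome genes are
   then ranked as candidate targets: strong, significant association
   with the index in the responsive model but no significant association
   in the poorly responsive one.
5. **Spatial infiltration**: phenotype gating from marker positivity
   (CD8 T cells, B cells, TAMs, CAFs) and cell densities in fixed-width
   distance bands from the tumor interface (default 25 × 20 µm bands
   over a 500 µm range).

A synthetic-data module generates fiber images, two-model expression
cohorts and spatial point patterns with known ground truth (planted
signature effects, metric–driver correlations via a Gaussian copula,
density gradients), so that every stage is testable against recoverable
truth.

## Worked example

```r
library(ecmtme)

## image stage: one synthetic fiber image through the full metric panel
fi <- simulate_fiber_image(n_fibers = 12, curvature_param = 0.08,
                           thickness_px = 3, seed = 7, size = c(256, 256))
ecm_metrics(img = fi$image)
#> total_length_px 658.63   n_branchpoints 88   n_endpoints 24
#> norm_branchpoints 0.134  curvature10 9.17    hdm_fraction 0.051
#> mean_gap_area_px2 431.6  lacunarity 6.51     bcfd 1.32
#> fiber_thickness_px 5.05  haralick_contrast 5.06 ...

## cohort stage: planted ground truth recovered end to end
sg <- synthetic_signatures()
co <- simulate_cohort(sg$universe, sg$signatures, n_per_model = 15,
        planted_metric_correlations = c(mean_gap_area_px2 = 0.9,
          lacunarity = 0.9, hdm_fraction = -0.9, total_length_px = -0.9),
        planted_target_genes = c("gene0150", "gene0151"), seed = 1)
pipe <- structure_pipeline(co, sg$signatures,
                           target_genes = sprintf("gene%04d", 150:160))
pipe$screen[, 1:5]
#>              metric spearman_r  p_value  n     sign
#> 1 mean_gap_area_px2      0.943 0.000000 15 positive
#> 2        lacunarity      0.886 0.000000 15 positive
#> 3      hdm_fraction     -0.896 0.000000 15 negative
#> 4   total_length_px     -0.829 0.000188 15 negative
head(pipe$targets[, c("gene", "r_modelA", "p_modelA", "p_modelB",
                      "candidate")], 3)
#>       gene r_modelA p_modelA p_modelB candidate
#> 1 gene0150    0.886  0.00000    0.783      TRUE
#> 2 gene0151    0.732  0.00273    0.450      TRUE
#> 3 gene0159    0.229  0.41142    0.584     FALSE
```

The screen recovers the four planted metric–score correlations with the
planted signs; the two planted target genes (correlated with the latent
driver in model A only) are flagged as candidates and the unplanted
genes are not. On the same cohort the recovered structure index tracks
the latent anti-TME driver at Spearman r = 0.975 and correlates
negatively (r = −0.79) with the simulated tumor weight, the qualitative
pattern expected of a response-linked index.

A thin command-line wrapper over the same functions ships in
`inst/scripts/ecmtme-cli.R` (subcommands `simulate-fibers`, `metrics`,
`simulate-cohort`, `score`, `integrate`, `spatial`); every stage is
byte-deterministic given its seed and inputs.

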