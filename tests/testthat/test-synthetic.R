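# Ground-truth generators: determinism, degenerate cases, and recovery
# of the planted structure by the downstream operations.

test_that("fiber image generation is deterministic and validates inputs", {
  a <- simulate_fiber_image(8, 0.1, seed = 9, size = c(96, 96))
  b <- simulate_fiber_image(8, 0.1, seed = 9, size = c(96, 96))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c2 <- simulate_fiber_image(8, 0.1, seed = 10, size = c(96, 96))
  expect_false(identical(a$mask, c2$mask))

  expect_error(simulate_fiber_image(3, size = c(32, 32)), "64")
  expect_error(simulate_fiber_image(3, thickness_px = 96,
                                    size = c(96, 96)), "thickness")
})

test_that("zero fibers give an all-background mask with zero HDM-ish panel", {
  fi <- simulate_fiber_image(0, seed = 2, size = c(96, 96))
  expect_false(any(fi$mask))
  met <- ecm_metrics(mask = fi$mask)
  expect_equal(met$total_length_px, 0)
  expect_equal(met$hdm_fraction, 0)
})

test_that("a straight single fiber has zero curvature at every window", {
  fi <- simulate_fiber_image(1, curvature_param = 0, thickness_px = 1,
                             fill_fraction = 0.5, seed = 3,
                             size = c(128, 128))
  sk <- skeletonize(fi$mask)
  expect_gt(sk$total_length_px, 40)
  for (w in c(10, 20)) {
    expect_equal(curvature(sk, w), 0)
  }
})

test_that("measured curvature orders with the curvature parameter", {
  for (seed in c(1, 2)) {
    lo <- simulate_fiber_image(6, 0.02, thickness_px = 1,
                               fill_fraction = 0.25, seed = seed,
                               size = c(192, 192))
    hi <- simulate_fiber_image(6, 0.2, thickness_px = 1,
                               fill_fraction = 0.25, seed = seed,
                               size = c(192, 192))
    c_lo <- curvature(skeletonize(lo$mask), 10)
    c_hi <- curvature(skeletonize(hi$mask), 10)
    expect_gt(c_hi, c_lo)
  }
})

test_that("cohort generation is deterministic and validates ground truth", {
  sg <- default_sigs()
  a <- simulate_cohort(sg$universe, sg$signatures, n_per_cell = 3,
                       planted_metric_correlations = c(m1 = 0.5),
                       seed = 11)
  b <- simulate_cohort(sg$universe, sg$signatures, n_per_cell = 3,
                       planted_metric_correlations = c(m1 = 0.5),
                       seed = 11)
  expect_identical(a$expr, b$expr)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$tumor_weight_g, b$tumor_weight_g)

  expect_error(simulate_cohort(sg$universe, sg$signatures,
                               planted_metric_correlations = c(m1 = 1.2)),
               "\\[-1, 1\\]")
  expect_error(simulate_cohort(sg$universe, sg$signatures,
                               planted_metric_correlations = c(m1 = 0.5),
                               metric_names = c("m2")),
               "unknown metric")
  expect_error(simulate_cohort(sg$universe, sg$signatures,
                               planted_metric_correlations = c(m1 = 0.5),
                               planted_target_genes = sg$universe[1]),
               "overlap")
})

test_that("n_per_model distributes samples over design cells", {
  sg <- default_sigs()
  co <- simulate_cohort(sg$universe, sg$signatures, n_per_model = 15,
                        planted_metric_correlations = c(m1 = 0.5),
                        seed = 1)
  expect_equal(sum(co$samples$model == "A"), 15)
  expect_equal(sum(co$samples$model == "B"), 15)
  expect_true(all(table(co$samples$model, co$samples$arm) %in% c(7, 8)))
})

test_that("a zero signature effect leaves the arms exchangeable", {
  sg <- default_sigs()
  co <- simulate_cohort(sg$universe, sg$signatures, n_per_cell = 10,
                        signature_effect = 0,
                        planted_metric_correlations = c(m1 = 0),
                        seed = 19)
  sc <- score_collection(co$expr, sg$signatures)$anti_TME
  tr <- co$samples$arm == "treated" & co$samples$model == "A"
  ct <- co$samples$arm == "control" & co$samples$model == "A"
  expect_gt(stats::wilcox.test(sc[tr], sc[ct])$p.value, 0.01)
})

test_that("a positive signature effect raises treated model-A scores", {
  sg <- default_sigs()
  wins <- 0
  for (seed in 1:20) {
    co <- simulate_cohort(sg$universe, sg$signatures, n_per_cell = 3,
                          signature_effect = 1.5,
                          planted_metric_correlations = c(m1 = 0),
                          seed = seed)
    sc <- score_collection(co$expr, sg$signatures)$anti_TME
    tr <- co$samples$arm == "treated" & co$samples$model == "A"
    ct <- co$samples$arm == "control" & co$samples$model == "A"
    wins <- wins + (mean(sc[tr]) > mean(sc[ct]))
  }
  # sign test: 20/20 wins under H0 has p = 2^-20
  expect_gte(wins, 18)
})

test_that("cell maps respect the density gradient and determinism", {
  region <- rectangular_region(400, 400)
  a <- simulate_cell_map(500, region, gradient = -2, seed = 7)
  b <- simulate_cell_map(500, region, gradient = -2, seed = 7)
  expect_identical(a, b)

  # negative gradient: inner bands denser, trend negative across replicates
  trend <- vapply(1:20, function(s) {
    cm <- simulate_cell_map(600, region, gradient = -100, seed = s)
    prof <- infiltration_profile(cm, region, band_width_um = 20,
                                 n_bands = 5)
    tot <- stats::aggregate(density_mm2 ~ band, prof, sum)
    cor(tot$band, tot$density_mm2, method = "spearman")
  }, numeric(1))
  expect_lt(mean(trend), 0)
  expect_gt(mean(trend < 0), 0.8)

  # planted phenotype mix is recovered exactly by the gates
  cm <- simulate_cell_map(2000, region, seed = 13)
  expect_equal(assign_phenotypes(cm), cm$true_phenotype)

  expect_error(simulate_cell_map(10, region,
                                 phenotype_mix = c("TAM" = 0.7)),
               "summing to 1")
})

test_that("requested counts are Poisson around the exponentiated means", {
  sg <- default_sigs()
  co <- simulate_cohort(sg$universe, sg$signatures, n_per_cell = 2,
                        planted_metric_correlations = c(m1 = 0),
                        seed = 23, counts = TRUE)
  expect_true(all(co$counts >= 0))
  expect_equal(dim(co$counts), dim(co$expr))
  # cpm filter is exercisable on the counts
  kept <- cpm_filter(co$counts)
  expect_gt(nrow(kept), 0)
})
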