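## Synthetic ground-truth generators: fiber images (random-walk
## polylines with tunable curvature and thickness), two-model expression
## cohorts with planted signature effects, metric correlations and
## target genes, and spatial point patterns with density gradients from
## a region boundary. Every generator draws from seeds derived from a
## single master seed and leaves the caller's RNG state untouched.

#' Simulate a fibrous ECM-like image with known ground truth
#'
#' Fibers are biased random walks: per unit step the walking direction
#' turns by a Gaussian angle with standard deviation `curvature_param`
#' (radians per step), so curvature is tunable from perfectly straight
#' (0) upward. Centerlines are dilated to `thickness_px` with a
#' Euclidean disk, composed into a gray image (bright fibers on a dark
#' background with mild Gaussian noise), and the returned mask is the
#' binarization of that image. Regenerating with identical parameters
#' yields a bit-identical image.
#'
#' @param n_fibers number of fibers (0 gives an all-background image).
#' @param curvature_param per-step turning-angle SD in radians (>= 0).
#' @param thickness_px fiber thickness in pixels (>= 1, less than the
#'   smallest image dimension).
#' @param fill_fraction target foreground fraction in (0, 1]; sets the
#'   total walk length.
#' @param seed integer seed.
#' @param size image size, `c(rows, cols)`, each >= 64.
#' @return List of class `fiber_image`: `image` (matrix, [0, 255]),
#'   `mask` (logical), `ground_truth` (the arguments).
#' @export
simulate_fiber_image <- function(n_fibers, curvature_param = 0.1,
                                 thickness_px = 3, fill_fraction = 0.15,
                                 seed = 1, size = c(256, 256)) {
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 64)) stop("size must be at least 64 x 64")
  if (thickness_px < 1 || thickness_px >= min(size))
    stop("thickness_px must be in [1, min(size))")
  if (curvature_param < 0) stop("curvature_param must be >= 0")
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  gt <- list(n_fibers = n_fibers, curvature_param = curvature_param,
             thickness_px = thickness_px, fill_fraction = fill_fraction,
             seed = seed, size = size)
  nr <- size[1]; nc <- size[2]
  center <- matrix(FALSE, nr, nc)
  withr::with_seed(derive_seed(seed, "fiber"), {
    if (n_fibers > 0) {
      steps <- max(16, round(fill_fraction * nr * nc /
                               (thickness_px * n_fibers)))
      for (f in seq_len(n_fibers)) {
        y <- runif(1, thickness_px + 1, nr - thickness_px)
        x <- runif(1, thickness_px + 1, nc - thickness_px)
        dir <- runif(1, 0, 2 * pi)
        turns <- rnorm(steps, 0, curvature_param)
        for (s in seq_len(steps)) {
          center[round(y), round(x)] <- TRUE
          dir <- dir + turns[s]
          y2 <- y + sin(dir); x2 <- x + cos(dir)
          if (y2 < 1 || y2 > nr || x2 < 1 || x2 > nc) break
          y <- y2; x <- x2
        }
      }
    }
    fg <- center
    if (any(center) && thickness_px > 1) {
      edt <- as.matrix(EBImage::distmap((!center) * 1))
      fg <- center | edt <= (thickness_px - 1) / 2
    }
    img <- ifelse(fg, 220, 25) + rnorm(nr * nc, 0, 8)
    img <- matrix(pmin(pmax(round(img), 0), 255), nr, nc)
  })
  mask <- binarize(img, 128)
  structure(list(image = img, mask = mask, ground_truth = gt),
            class = "fiber_image")
}

# Pearson correlation giving a target Spearman correlation under a
# Gaussian copula: rho_P = 2 sin(pi rho_S / 6).
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# rank-normal scores of v (Gaussian copula anchor): preserves ranks, so
# any monotone transform downstream keeps the planted Spearman r
rank_normal <- function(v) qnorm((rank(v, ties.method = "first") - 0.5) /
                                   length(v))

# draw a vector with planted Spearman correlation rho_s to anchor z
copula_with <- function(z, rho_s) {
  rho_p <- spearman_to_pearson(rho_s)
  u <- rank_normal(z)
  rho_p * u + sqrt(1 - rho_p^2) * rnorm(length(z))
}

#' Simulate a two-model expression cohort with planted ground truth
#'
#' Samples span two models (A = chemo-responsive, B = poorly responsive)
#' times two arms (control/treated) times three timepoints. A latent
#' per-sample anti-TME driver `z ~ N(0, 1)` is shifted upward by
#' `signature_effect` in treated model-A samples; the genes of the
#' composite anti-TME signature track the driver on the log2 scale (so
#' treated model-A samples carry the planted signature up-regulation,
#' and an effect of 0 makes the arms exchangeable). Each named ECM
#' metric is simulated with its planted Spearman correlation to the
#' driver via a Gaussian copula (in model A; metrics are independent
#' noise in model B), planted target genes are correlated with the
#' driver in model A only, and tumor weight is a decreasing function of
#' the driver. The same seed reproduces the cohort bit-identically.
#'
#' @param gene_universe character vector of gene ids.
#' @param signatures a [signature_collection()]; its genes must be in
#'   the universe.
#' @param n_per_cell samples per model x arm x timepoint cell (ignored
#'   when `n_per_model` is given).
#' @param n_per_model alternative: total samples per model, distributed
#'   round-robin over the 6 cells.
#' @param signature_effect log2-scale driver shift in treated model-A
#'   samples (default 0).
#' @param planted_metric_correlations named numeric vector: target
#'   Spearman r (in [-1, 1]) between each named metric and the driver.
#' @param metric_names all metric columns to simulate (default: the
#'   planted names; must contain them).
#' @param planted_target_genes genes (not in the anti-TME union) given
#'   correlation `target_correlation` with the driver in model A only.
#' @param target_correlation Spearman r for planted targets (default
#'   0.9).
#' @param noise_sd log2-scale expression noise SD (default 0.5).
#' @param driver_coupling log2 units of anti-TME gene shift per driver
#'   SD (default 1).
#' @param seed integer master seed.
#' @param counts also draw Poisson counts from the exponentiated means
#'   (default `FALSE`).
#' @return List of class `synthetic_cohort`: `expr` (genes x samples,
#'   log2), optional `counts`, `samples` (sample table with model, arm,
#'   timepoint, batch), `metrics` (samples x metrics), `tumor_weight_g`,
#'   `driver` (the latent ground truth), `ground_truth`.
#' @export
simulate_cohort <- function(gene_universe, signatures, n_per_cell = 5,
                            n_per_model = NULL, signature_effect = 0,
                            planted_metric_correlations = numeric(0),
                            metric_names = NULL,
                            planted_target_genes = character(0),
                            target_correlation = 0.9, noise_sd = 0.5,
                            driver_coupling = 1, seed = 1,
                            counts = FALSE) {
  stopifnot(inherits(signatures, "signature_collection"))
  sig_genes <- anti_tme_genes(signatures)
  if (!all(unlist(signatures$sets) %in% gene_universe))
    stop("signature genes must be a subset of the gene universe")
  if (length(planted_metric_correlations) &&
      (is.null(names(planted_metric_correlations)) ||
       any(names(planted_metric_correlations) == "")))
    stop("planted metric correlations must be named")
  if (any(abs(planted_metric_correlations) > 1) ||
      abs(target_correlation) > 1)
    stop("planted correlations must lie in [-1, 1]")
  if (is.null(metric_names)) metric_names <- names(planted_metric_correlations)
  unknown <- setdiff(names(planted_metric_correlations), metric_names)
  if (length(unknown))
    stop("unknown metric name: ", paste(unknown, collapse = ", "))
  if (length(metric_names) == 0)
    stop("at least one metric name is required")
  bad <- intersect(planted_target_genes, sig_genes)
  if (length(bad))
    stop("planted targets overlap the anti-TME union: ",
         paste(bad, collapse = ", "))
  if (!all(planted_target_genes %in% gene_universe))
    stop("planted target genes must be in the gene universe")

  # arm varies fastest so that round-robin extras balance the arms
  cells <- expand.grid(arm = c("control", "treated"),
                       timepoint = c("TP1", "TP2", "TP3"),
                       model = c("A", "B"), stringsAsFactors = FALSE)
  cells <- cells[, c("model", "arm", "timepoint")]
  if (is.null(n_per_model)) {
    reps <- rep(n_per_cell, nrow(cells))
  } else {
    # distribute n_per_model round-robin over the 6 cells of each model
    reps <- integer(nrow(cells))
    for (m in c("A", "B")) {
      rows <- which(cells$model == m)
      base <- n_per_model %/% length(rows)
      extra <- n_per_model %% length(rows)
      reps[rows] <- base + (seq_along(rows) <= extra)
    }
  }
  smp <- cells[rep(seq_len(nrow(cells)), reps), , drop = FALSE]
  rownames(smp) <- NULL
  smp$sample <- sprintf("%s_%s_%s_r%02d", smp$model, smp$arm,
                        smp$timepoint,
                        unlist(lapply(reps, seq_len)))
  smp$batch <- rep_len(c("b1", "b2"), nrow(smp))
  smp <- smp[, c("sample", "model", "arm", "timepoint", "batch")]
  S <- nrow(smp)
  G <- length(gene_universe)

  gt <- list(n_per_cell = if (is.null(n_per_model)) n_per_cell else NA,
             n_per_model = n_per_model, signature_effect = signature_effect,
             planted_metric_correlations = planted_metric_correlations,
             planted_target_genes = planted_target_genes,
             target_correlation = target_correlation, noise_sd = noise_sd,
             driver_coupling = driver_coupling, seed = seed)

  is_a <- smp$model == "A"

  baseline <- withr::with_seed(derive_seed(seed, "baseline"),
                               runif(G, 3, 8))
  names(baseline) <- gene_universe

  driver <- withr::with_seed(derive_seed(seed, "driver"), rnorm(S)) +
    signature_effect * (is_a & smp$arm == "treated")
  names(driver) <- smp$sample

  expr <- withr::with_seed(derive_seed(seed, "noise"),
    matrix(rnorm(G * S, 0, noise_sd), G, S)) + baseline
  dimnames(expr) <- list(gene_universe, smp$sample)
  expr[sig_genes, ] <- expr[sig_genes, , drop = FALSE] +
    rep(driver_coupling * driver, each = length(sig_genes))

  if (length(planted_target_genes)) {
    withr::with_seed(derive_seed(seed, "targets"), {
      for (g in planted_target_genes) {
        v <- copula_with(driver[is_a], target_correlation)
        expr[g, is_a] <- baseline[g] + noise_sd * v
      }
    })
  }

  metrics <- withr::with_seed(derive_seed(seed, "metrics"), {
    m <- matrix(rnorm(S * length(metric_names)), S, length(metric_names))
    dimnames(m) <- list(smp$sample, metric_names)
    for (nm in names(planted_metric_correlations)) {
      m[is_a, nm] <- copula_with(driver[is_a],
                                 planted_metric_correlations[[nm]])
    }
    exp(0.8 * m)    # positive, right-skewed, metric-like scale
  })

  tumor_weight <- withr::with_seed(derive_seed(seed, "weight"),
    exp(-0.5 * driver + rnorm(S, 0, 0.3)))
  names(tumor_weight) <- smp$sample

  out <- list(expr = expr, samples = smp,
              metrics = as.data.frame(metrics),
              tumor_weight_g = tumor_weight, driver = driver,
              ground_truth = gt)
  if (counts) {
    out$counts <- withr::with_seed(derive_seed(seed, "counts"), {
      cm <- matrix(rpois(G * S, lambda = 2^expr), G, S)
      dimnames(cm) <- dimnames(expr)
      cm
    })
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples;", ncol(x$metrics), "metrics\n")
  invisible(x)
}

#' A synthetic signature collection and gene universe for testing
#'
#' Builds a gene universe of `n_genes` synthetic ids plus four synthetic
#' member signatures (M1, Th1, anti-tumor cytokines, B cells) of
#' `set_size` genes each, drawn from the head of the universe. These are
#' placeholders with the right structure, not curated biology.
#'
#' @param n_genes universe size (default 300).
#' @param set_size genes per member set (default 10).
#' @return List with `universe` and `signatures`
#'   (a [signature_collection()]).
#' @export
synthetic_signatures <- function(n_genes = 300, set_size = 10) {
  universe <- sprintf("gene%04d", seq_len(n_genes))
  idx <- split(seq_len(4 * set_size), rep(1:4, each = set_size))
  sets <- list(M1 = universe[idx[[1]]], Th1 = universe[idx[[2]]],
               Anti_tumor_cytokines = universe[idx[[3]]],
               B_cells = universe[idx[[4]]])
  list(universe = universe, signatures = signature_collection(sets))
}

#' Simulate a spatial cell map with a density gradient from the tumor edge
#'
#' Cells are placed on one side of the tumor interface with intensity
#' linear in the distance from the boundary,
#' `lambda(d) = max(0, lambda0 + gradient * d)` with `d` in micrometers
#' and `lambda0 = n_cells / side area` in cells/mm^2; `gradient = 0`
#' gives a homogeneous Poisson-like pattern. Each cell gets a phenotype
#' drawn from `phenotype_mix` and the canonical marker pattern for that
#' phenotype, so that the gating rules of [assign_phenotypes()] recover
#' the mix exactly.
#'
#' @param n_cells number of cells.
#' @param region a [region_geometry()].
#' @param gradient signed density slope in cells/mm^2 per micrometer of
#'   distance from the boundary.
#' @param phenotype_mix named fractions over
#'   `CD8 T cell`, `B cell`, `TAM`, `CAF`, `other`; must sum to 1.
#' @param side `"inside"` (default) or `"outside"` the tumor region.
#' @param seed integer seed.
#' @return Data.frame of class `cell_table`: `cell_id`, `x_um`, `y_um`,
#'   the 12 logical marker columns, and `true_phenotype`.
#' @export
simulate_cell_map <- function(n_cells, region, gradient = 0,
                              phenotype_mix = c("CD8 T cell" = 0.15,
                                                "B cell" = 0.10,
                                                "TAM" = 0.25, "CAF" = 0.20,
                                                "other" = 0.30),
                              side = c("inside", "outside"), seed = 1) {
  side <- match.arg(side)
  stopifnot(inherits(region, "region_geometry"), n_cells >= 0)
  if (any(phenotype_mix < 0) || abs(sum(phenotype_mix) - 1) > 1e-8)
    stop("phenotype_mix must be nonnegative fractions summing to 1")
  d <- region$distance_um
  on_side <- if (side == "inside") d <= 0 else d > 0
  on_side <- on_side & region$tissue_mask
  if (!any(on_side)) stop("no pixels on the requested side of the boundary")

  markers <- marker_panel()
  empty <- as.data.frame(c(
    list(cell_id = character(), x_um = numeric(), y_um = numeric()),
    setNames(rep(list(logical()), length(markers)), markers),
    list(true_phenotype = character())))
  if (n_cells == 0) return(structure(empty, class = c("cell_table",
                                                      "data.frame")))

  area_mm2 <- sum(on_side) * region$um_per_px^2 / 1e6
  lambda0 <- n_cells / area_mm2
  w <- pmax(0, lambda0 + gradient * abs(d))
  w[!on_side] <- 0
  if (sum(w) == 0) stop("intensity is zero everywhere on the chosen side")

  withr::with_seed(derive_seed(seed, "cells"), {
    px <- sample(which(on_side), n_cells, replace = TRUE,
                 prob = w[on_side])
    nr <- nrow(d)
    iy <- (px - 1) %% nr + 1
    ix <- (px - 1) %/% nr + 1
    x_um <- (ix - runif(n_cells)) * region$um_per_px
    y_um <- (iy - runif(n_cells)) * region$um_per_px
    phen <- sample(names(phenotype_mix), n_cells, replace = TRUE,
                   prob = phenotype_mix)
  })

  mk <- matrix(FALSE, n_cells, length(markers),
               dimnames = list(NULL, markers))
  mk[phen == "CD8 T cell", "CD8"] <- TRUE
  mk[phen == "B cell", "B220"] <- TRUE
  mk[phen == "TAM", "CD206"] <- TRUE
  mk[phen == "CAF", "aSMA"] <- TRUE
  out <- cbind(data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                          x_um = x_um, y_um = y_um,
                          stringsAsFactors = FALSE),
               as.data.frame(mk),
               data.frame(true_phenotype = phen, stringsAsFactors = FALSE))
  structure(out, class = c("cell_table", "data.frame"))
}

#' A simple rectangular tissue with a centered rectangular tumor region
#'
#' Convenience geometry for simulations and examples: an `nr x nc`
#' tissue grid whose central rectangle (half the extent in each
#' dimension) is the tumor region.
#'
#' @param nr,nc grid size in pixels.
#' @param um_per_px calibration (default 1).
#' @return A [region_geometry()].
#' @export
rectangular_region <- function(nr = 600, nc = 600, um_per_px = 1) {
  tumor <- matrix(FALSE, nr, nc)
  tumor[(nr %/% 4):(3 * nr %/% 4), (nc %/% 4):(3 * nc %/% 4)] <- TRUE
  region_geometry(tumor, um_per_px)
}
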