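## Haralick texture: gray-level co-occurrence matrices over a quantized
## intensity range and the five summary statistics used for stained-
## tissue texture panels, plus the ratio-of-control-medians batch
## normalization for features measured across staining experiments.

#' Gray-level co-occurrence matrix
#'
#' Intensities are quantized into `levels` equal-width bins over the
#' (masked) min-max range, then pixel pairs at the given offset are
#' counted, optionally symmetrized (transpose added), and normalized to
#' sum to 1.
#'
#' @param img numeric matrix.
#' @param offset integer pair `(dy, dx)`, nonzero.
#' @param levels number of gray levels (default 16).
#' @param symmetric add the transposed counts (default `TRUE`).
#' @param mask optional logical matrix; pairs are counted only when both
#'   pixels are inside the mask.
#' @return `levels x levels` matrix of pair probabilities, with
#'   attributes `offset` and `symmetric`.
#' @export
glcm <- function(img, offset = c(0, 1), levels = 16, symmetric = TRUE,
                 mask = NULL) {
  stopifnot(is.matrix(img), length(offset) == 2)
  if (all(offset == 0)) stop("offset must be nonzero")
  if (levels < 2) stop("levels must be >= 2")
  nr <- nrow(img); nc <- ncol(img)
  if (abs(offset[1]) >= nr || abs(offset[2]) >= nc)
    stop("image smaller than offset")
  q <- quantize_gray(img, levels, mask)
  ys <- seq_len(nr - abs(offset[1]))
  xs <- seq_len(nc - abs(offset[2]))
  if (offset[1] < 0) ys <- ys + abs(offset[1])
  if (offset[2] < 0) xs <- xs + abs(offset[2])
  i <- q[ys, xs, drop = FALSE]
  j <- q[ys + offset[1], xs + offset[2], drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) stop("no pixel pairs inside the mask at this offset")
  counts <- matrix(0, levels, levels)
  tab <- table(factor(i[ok], levels = 1:levels),
               factor(j[ok], levels = 1:levels))
  counts <- counts + as.matrix(tab)
  if (symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  attr(P, "offset") <- offset
  attr(P, "symmetric") <- symmetric
  P
}

# quantize over the masked min-max range; outside-mask pixels become NA
quantize_gray <- function(img, levels, mask = NULL) {
  v <- img
  if (!is.null(mask)) v[!mask] <- NA
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) {
    q <- matrix(1L, nrow(img), ncol(img))
  } else {
    q <- pmin(floor((v - rng[1]) / diff(rng) * levels) + 1L, levels)
  }
  if (!is.null(mask)) q[!mask] <- NA
  q
}

#' Haralick statistics of a normalized GLCM
#'
#' Computes contrast `sum P (i-j)^2`, energy (angular second moment)
#' `sum P^2`, homogeneity `sum P / (1 + |i-j|)`, entropy
#' `-sum P log2 P` (with `0 log 0 = 0`), and the standard GLCM
#' correlation from the marginal means and standard deviations
#' (undefined, `NA`, when a marginal has zero variance).
#'
#' @param g a [glcm()] result (entries must sum to 1).
#' @return Named list: `haralick_contrast`, `haralick_correlation`,
#'   `haralick_energy`, `haralick_homogeneity`, `haralick_entropy`.
#' @export
haralick_features <- function(g) {
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  if (abs(sum(g) - 1) > 1e-9) stop("GLCM must be normalized")
  L <- nrow(g)
  i <- matrix(1:L, L, L)
  j <- t(i)
  contrast <- sum(g * (i - j)^2)
  energy <- sum(g^2)
  homog <- sum(g / (1 + abs(i - j)))
  nz <- g > 0
  entropy <- -sum(g[nz] * log2(g[nz]))
  pi_ <- rowSums(g); pj <- colSums(g)
  mi <- sum((1:L) * pi_); mj <- sum((1:L) * pj)
  si <- sqrt(sum((1:L)^2 * pi_) - mi^2)
  sj <- sqrt(sum((1:L)^2 * pj) - mj^2)
  corr <- if (si < 1e-12 || sj < 1e-12) NA_real_ else
    (sum(i * j * g) - mi * mj) / (si * sj)
  list(haralick_contrast = contrast, haralick_correlation = corr,
       haralick_energy = energy, haralick_homogeneity = homog,
       haralick_entropy = entropy)
}

#' Direction-averaged Haralick features for one image
#'
#' Computes [haralick_features()] for each offset (defaults to the four
#' standard directions at distance 1) and averages each statistic.
#'
#' @param img numeric matrix.
#' @param offsets list of `(dy, dx)` pairs; default
#'   `(0,1), (1,0), (1,1), (1,-1)`.
#' @inheritParams glcm
#' @return Named list of the five averaged statistics.
#' @export
glcm_features <- function(img, offsets = NULL, levels = 16,
                          symmetric = TRUE, mask = NULL) {
  if (is.null(offsets))
    offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  per <- lapply(offsets, function(o)
    haralick_features(glcm(img, o, levels, symmetric, mask)))
  stats_names <- names(per[[1]])
  out <- lapply(stats_names, function(nm)
    mean(vapply(per, `[[`, numeric(1), nm), na.rm = TRUE))
  setNames(out, stats_names)
}

#' Batch-normalize texture features by ratio of control medians
#'
#' For each feature and each batch, all of the batch's values are
#' multiplied by `median(reference-batch controls) / median(batch
#' controls)`, so that after normalization every batch's control median
#' equals the reference batch's control median exactly. The reference
#' batch is unchanged.
#'
#' @param table data.frame with feature columns plus batch and group
#'   columns.
#' @param features character vector of feature column names.
#' @param batch name of the batch (experiment) column.
#' @param group name of the group column.
#' @param control value of `group` marking control samples.
#' @param reference_batch batch used as reference.
#' @return The table with normalized feature columns.
#' @export
batch_normalize <- function(table, features, batch = "batch",
                            group = "group", control = "control",
                            reference_batch) {
  stopifnot(is.data.frame(table), all(features %in% names(table)),
            batch %in% names(table), group %in% names(table))
  batches <- unique(table[[batch]])
  if (!reference_batch %in% batches)
    stop("reference batch not present: ", reference_batch)
  ctrl <- table[[group]] == control
  for (b in batches) {
    if (!any(ctrl & table[[batch]] == b))
      stop("batch has no control samples: ", b)
  }
  out <- table
  for (f in features) {
    ref_med <- median(table[[f]][ctrl & table[[batch]] == reference_batch])
    for (b in setdiff(batches, reference_batch)) {
      b_med <- median(table[[f]][ctrl & table[[batch]] == b])
      if (b_med == 0) stop("zero control median in batch ", b,
                           " for feature ", f)
      sel <- table[[batch]] == b
      out[[f]][sel] <- table[[f]][sel] * ref_med / b_med
    }
  }
  out
}
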