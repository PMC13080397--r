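## The per-image ECM metric panel: fiber-network metrics from the
## skeleton, curvature at fixed chord windows, HDM, gap structure,
## lacunarity, box-counting fractal dimension, derived fiber thickness,
## and (when a gray image is available) Haralick texture features.

#' Default configuration for the ECM metric panel
#'
#' @param hdm_threshold saturation intensity for the high-density-matrix
#'   fraction (default 140 on the 0-255 scale).
#' @param binarize_threshold threshold passed to [binarize()] when only a
#'   gray image is supplied (`"otsu"` or a number).
#' @param curvature_windows chord windows in pixels (default 10, 20, 30,
#'   40).
#' @param min_gap_radius_px smallest recorded gap radius (default 2).
#' @param glcm_levels,glcm_offsets Haralick texture parameters, see
#'   [glcm_features()].
#' @param include_texture compute Haralick features when a gray image is
#'   available (default `TRUE`).
#' @return A named list of settings.
#' @export
metrics_config <- function(hdm_threshold = 140, binarize_threshold = "otsu",
                           curvature_windows = c(10, 20, 30, 40),
                           min_gap_radius_px = 2, glcm_levels = 16,
                           glcm_offsets = NULL, include_texture = TRUE) {
  list(hdm_threshold = hdm_threshold,
       binarize_threshold = binarize_threshold,
       curvature_windows = curvature_windows,
       min_gap_radius_px = min_gap_radius_px,
       glcm_levels = glcm_levels, glcm_offsets = glcm_offsets,
       include_texture = include_texture)
}

#' Compute the full ECM structural metric panel for one image
#'
#' Accepts a gray image, a binary mask, or both. When only an image is
#' given the mask is derived by [binarize()]; when only a mask is given,
#' HDM falls back to the mask's foreground fraction (every foreground
#' pixel treated as saturated) and texture features are skipped. Fiber
#' thickness is derived as `hdm * image_area / total_length` (high-
#' density matrix times image area over total fiber length). Undefined
#' metrics (e.g. curvature with no eligible fiber, lacunarity of an empty
#' mask) are `NA`, never 0.
#'
#' @param img numeric matrix in [0, 255], or `NULL`.
#' @param mask logical matrix, or `NULL`.
#' @param config see [metrics_config()].
#' @return A one-row data.frame with stable column names:
#'   `total_length_px`, `n_branchpoints`, `n_endpoints`,
#'   `norm_branchpoints`, `norm_endpoints`, `avg_fiber_length_px`,
#'   `curvature10` ... `curvature40`, `hdm_fraction`,
#'   `mean_gap_area_px2`, `lacunarity`, `bcfd`, `fiber_thickness_px`,
#'   plus `haralick_*` columns when texture is computed.
#' @export
ecm_metrics <- function(img = NULL, mask = NULL, config = metrics_config()) {
  if (is.null(img) && is.null(mask))
    stop("supply a gray image, a binary mask, or both")
  if (is.null(mask)) mask <- binarize(img, config$binarize_threshold)
  if (!is.null(img) && !all(dim(img) == dim(mask)))
    stop("image and mask shapes differ")

  sk <- skeletonize(mask)
  fm <- fiber_metrics(sk)
  cur <- vapply(config$curvature_windows, function(w) curvature(sk, w),
                numeric(1))
  names(cur) <- paste0("curvature", config$curvature_windows)
  h <- if (!is.null(img)) hdm(img, config$hdm_threshold) else mean(mask)
  gaps <- gap_analysis(mask, config$min_gap_radius_px)
  lac <- lacunarity(mask)
  fd <- box_counting_fd(mask)
  thick <- if (fm$total_length_px > 0)
    h * length(mask) / fm$total_length_px else NA_real_

  out <- cbind(fm, as.data.frame(as.list(cur)),
               data.frame(hdm_fraction = h,
                          mean_gap_area_px2 = gaps$mean_gap_area_px2,
                          lacunarity = lac$mean, bcfd = fd,
                          fiber_thickness_px = thick))
  if (!is.null(img) && isTRUE(config$include_texture)) {
    tex <- glcm_features(img, levels = config$glcm_levels,
                         offsets = config$glcm_offsets)
    out <- cbind(out, as.data.frame(as.list(tex)))
  }
  rownames(out) <- NULL
  out
}

#' Run the metric panel over a directory of images
#'
#' Reads every PNG/TIFF in `dir` (sorted by name) as a gray image,
#' computes [ecm_metrics()] for each, and optionally writes one row per
#' image to a TSV with stable column names.
#'
#' @param dir directory of images (or a character vector of file paths).
#' @param config see [metrics_config()].
#' @param out optional output TSV path.
#' @return The metrics data.frame (column `image` first), invisibly if
#'   `out` is given.
#' @export
metrics_for_images <- function(dir, config = metrics_config(), out = NULL) {
  paths <- if (length(dir) == 1 && dir.exists(dir))
    sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                    ignore.case = TRUE)) else sort(dir)
  if (length(paths) == 0) stop("no images found")
  rows <- lapply(paths, function(p)
    cbind(data.frame(image = basename(p), stringsAsFactors = FALSE),
          ecm_metrics(img = read_gray_image(p), config = config)))
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    write_tsv(res, out)
    return(invisible(res))
  }
  res
}
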