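## Images are plain numeric matrices with intensities in [0, 255]
## ([row, col] indexing); binary masks are logical matrices of the same
## shape. Pixel size calibration enters only in the spatial module.

#' Stain optical-density bases for color deconvolution
#'
#' Returns the 3x3 matrix of unit stain vectors (rows) used to unmix an
#' RGB brightfield image into stain channels, following the standard
#' Ruifrok & Johnston optical-density model. `"H-DAB"` separates
#' hematoxylin from the brown DAB chromogen; `"H-PAS"` separates
#' hematoxylin from the PAS/aniline-blue component used to read fibrillar
#' collagen out of trichrome stains. The third (residual) vector is the
#' normalized cross product of the first two.
#'
#' @param basis `"H-DAB"`, `"H-PAS"`, or `"custom"`.
#' @param custom for `basis = "custom"`, a 3x3 numeric matrix of stain
#'   vectors (rows; need not be unit length, they are normalized).
#' @return A 3x3 matrix with rownames naming the stain channels.
#' @export
stain_vectors <- function(basis = c("H-DAB", "H-PAS", "custom"),
                          custom = NULL) {
  basis <- match.arg(basis)
  m <- switch(basis,
    "H-DAB" = rbind(
      hematoxylin = c(0.650, 0.704, 0.286),
      dab         = c(0.268, 0.570, 0.776)
    ),
    "H-PAS" = rbind(
      hematoxylin = c(0.644211, 0.716556, 0.266844),
      pas         = c(0.175411, 0.972178, 0.154589)
    ),
    "custom" = {
      if (is.null(custom) || !is.matrix(custom) || !all(dim(custom) == 3))
        stop("`custom` must be a 3x3 matrix of stain vectors (rows)")
      custom[1:2, , drop = FALSE]
    }
  )
  if (basis == "custom" && nrow(custom) == 3 && any(custom[3, ] != 0)) {
    m <- custom
  } else {
    a <- m[1, ]; b <- m[2, ]
    res <- c(a[2] * b[3] - a[3] * b[2],
             a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
    m <- rbind(m, residual = res)
  }
  m <- m / sqrt(rowSums(m^2))
  if (abs(det(m)) < 1e-8) stop("stain vectors are not linearly independent")
  m
}

#' Unmix an RGB image into one stain channel
#'
#' Converts the image to optical density, `OD = -log10((I + 1) / 256)`
#' per RGB channel, and solves the linear unmixing problem against the
#' stain basis. The requested stain channel is returned either as raw
#' optical density, or rescaled to a [0, 255] gray image where 255
#' corresponds to the maximum representable single-channel OD
#' (`log10(256)`), so that denser staining maps to brighter pixels.
#'
#' @param rgb numeric array `h x w x 3` with values in [0, 255].
#' @param basis,custom passed to [stain_vectors()].
#' @param channel stain channel to extract: name (e.g. `"dab"`) or index.
#' @param output `"intensity"` (default, [0, 255] gray matrix) or `"od"`
#'   (unclipped optical density matrix).
#' @return A numeric matrix (one channel).
#' @export
deconvolve_stain <- function(rgb, basis = "H-DAB", channel = 2,
                             custom = NULL,
                             output = c("intensity", "od")) {
  output <- match.arg(output)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("`rgb` must be an h x w x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("RGB values must lie in [0, 255]")
  M <- stain_vectors(basis, custom)
  if (is.character(channel)) {
    channel <- match(channel, rownames(M))
    if (is.na(channel)) stop("unknown stain channel name")
  }
  if (channel < 1 || channel > 3) stop("channel must index one of 3 stains")
  d <- dim(rgb)
  od <- -log10((matrix(rgb, ncol = 3) + 1) / 256)  # N x 3
  conc <- od %*% solve(M)                           # stain concentrations
  ch <- matrix(conc[, channel], d[1], d[2])
  if (output == "od") return(ch)
  out <- ch / log10(256) * 255
  pmin(pmax(out, 0), 255)
}

#' Threshold a gray image into a binary mask
#'
#' @param img numeric matrix with intensities in [0, 255].
#' @param threshold numeric threshold in [0, 255], or `"otsu"` for
#'   automatic bimodal separation (Otsu's method).
#' @return Logical matrix, `TRUE` where `img >= threshold`.
#' @export
binarize <- function(img, threshold = "otsu") {
  stopifnot(is.matrix(img))
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(EBImage::Image(img / 255), levels = 256) * 255
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255] or \"otsu\"")
  m <- img >= threshold
  attr(m, "threshold") <- threshold
  m
}

#' High-density matrix fraction
#'
#' Fraction of pixels whose stain intensity is at or above a saturation
#' threshold -- the "high-density matrix" (HDM) readout of dense ECM.
#'
#' @param img numeric matrix in [0, 255].
#' @param saturation_threshold intensity threshold (default 140).
#' @return Fraction in [0, 1].
#' @export
hdm <- function(img, saturation_threshold = 140) {
  stopifnot(is.matrix(img))
  if (saturation_threshold < 0 || saturation_threshold > 255)
    stop("saturation_threshold must be in [0, 255]")
  mean(img >= saturation_threshold)
}

#' Read an image file as a gray matrix in [0, 255]
#'
#' PNG and TIFF are supported. RGB images are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B); an alpha channel, if present, is
#' dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric matrix in [0, 255].
#' @export
read_gray_image <- function(path) {
  a <- read_image_array(path)
  if (length(dim(a)) == 3) {
    a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  }
  a
}

#' Read an image file as an RGB array in [0, 255]
#' @param path file path ending in .png, .tif or .tiff.
#' @return Numeric array `h x w x 3` (or a matrix if the file is gray).
#' @export
read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  a <- a * 255
  if (length(dim(a)) == 3 && dim(a)[3] >= 3) a <- a[, , 1:3, drop = FALSE]
  if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
  a
}

#' Write a gray image or binary mask as PNG
#' @param img numeric matrix in [0, 255] or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (is.logical(img)) img <- img * 255
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
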