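## Gap structure of the fiber mask: greedy maximal inscribed circles in
## the background (from the Euclidean distance transform), gliding-box
## lacunarity, and box-counting fractal dimension.

#' Gap analysis: maximal inscribed background circles
#'
#' Finds gaps between fibers as greedy non-overlapping maximal inscribed
#' circles in the background: compute the Euclidean distance transform of
#' the background (distance to the nearest foreground pixel), take the
#' global maximum, record a circle of that radius and area `pi * r^2`,
#' zero the transform over its disk, and repeat while the maximal radius
#' is at least `min_gap_radius_px`.
#'
#' @param mask logical matrix (fiber foreground `TRUE`).
#' @param min_gap_radius_px smallest circle radius still counted as a gap
#'   (default 2).
#' @return List with `mean_gap_area_px2` (0 when no gaps) and `gaps`, a
#'   data.frame of circle centers (`y`, `x`), `radius_px` and `area_px2`.
#' @export
gap_analysis <- function(mask, min_gap_radius_px = 2) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- data.frame(y = integer(), x = integer(),
                      radius_px = numeric(), area_px2 = numeric())
  if (!any(mask) || all(mask))
    return(list(mean_gap_area_px2 = 0, gaps = empty))
  edt <- EBImage::distmap((!mask) * 1)   # distance to nearest fiber pixel
  edt <- as.matrix(edt)
  nr <- nrow(edt); nc <- ncol(edt)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  gaps <- empty
  repeat {
    r <- max(edt)
    if (r < min_gap_radius_px) break
    i <- which.max(edt)
    cy <- rows[i]; cx <- cols[i]
    gaps <- rbind(gaps, data.frame(y = cy, x = cx, radius_px = r,
                                   area_px2 = pi * r^2))
    edt[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- 0
  }
  list(mean_gap_area_px2 = if (nrow(gaps)) mean(gaps$area_px2) else 0,
       gaps = gaps)
}

#' Gliding-box lacunarity
#'
#' For each box size `r`, an `r x r` box glides over every position of
#' the mask; its mass `m` is the occupied pixel count, and
#' `Lambda(r) = E[m^2] / E[m]^2`. A homogeneous mask gives 1 at every
#' size; gappier masks give larger values. The summary value is the mean
#' of `Lambda(r)` over the box sizes.
#'
#' @param mask logical matrix.
#' @param box_sizes integer vector; default dyadic sizes 2, 4, 8, ... up
#'   to `min(dim(mask)) / 4`.
#' @return List with `lambda` (named per-size values) and `mean`. An
#'   empty mask gives `NA` (undefined, not 0).
#' @export
lacunarity <- function(mask, box_sizes = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (is.null(box_sizes)) {
    m <- min(dim(mask)) / 4
    box_sizes <- 2^(1:max(1, floor(log2(m))))
    box_sizes <- box_sizes[box_sizes <= m]
    if (length(box_sizes) == 0) box_sizes <- 2
  }
  if (!any(mask))
    return(list(lambda = setNames(rep(NA_real_, length(box_sizes)),
                                  box_sizes), mean = NA_real_))
  lam <- vapply(box_sizes, function(r) {
    if (r > min(dim(mask))) return(NA_real_)
    m <- box_sums(mask, r)
    mu <- mean(m)
    if (mu == 0) return(NA_real_)
    mean(m^2) / mu^2
  }, numeric(1))
  names(lam) <- box_sizes
  list(lambda = lam, mean = mean(lam, na.rm = TRUE))
}

# sliding r x r window sums via a summed-area table
box_sums <- function(mask, r) {
  m <- mask * 1
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  nr <- nrow(m); nc <- ncol(m)
  ys <- 1:(nr - r + 1); xs <- 1:(nc - r + 1)
  sat[ys + r, xs + r, drop = FALSE] - sat[ys, xs + r, drop = FALSE] -
    sat[ys + r, xs, drop = FALSE] + sat[ys, xs, drop = FALSE]
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes `N(eps)` on grids of dyadic box sizes anchored
#' at the image origin and reports the least-squares slope of `log N`
#' against `log(1/eps)`: near 1 for curves, near 2 for filled regions.
#'
#' @param mask logical matrix.
#' @param box_sizes dyadic sizes; default `1, 2, 4, ...` up to
#'   `min(dim(mask)) / 2`.
#' @return The fitted dimension, or `NA` for an empty mask.
#' @export
box_counting_fd <- function(mask, box_sizes = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(NA_real_)
  if (is.null(box_sizes)) {
    kmax <- max(1, floor(log2(min(dim(mask)) / 2)))
    box_sizes <- 2^(0:kmax)
  }
  fg <- which(mask, arr.ind = TRUE)
  N <- vapply(box_sizes, function(eps) {
    cells <- paste(floor((fg[, 1] - 1) / eps), floor((fg[, 2] - 1) / eps))
    length(unique(cells))
  }, numeric(1))
  keep <- N > 0
  if (sum(keep) < 2) return(NA_real_)
  unname(coef(lm(log(N[keep]) ~ log(1 / box_sizes[keep])))[2])
}
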