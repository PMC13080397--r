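# Fiber-structure metric panel: stain unmixing, skeleton geometry,
# curvature, gaps, lacunarity, fractal dimension, and the derived
# thickness, checked against analytic and enumeration oracles.

test_that("stain deconvolution inverts the optical-density model", {
  # pure white: OD ~ 0 in every stain channel
  white <- array(255, c(2, 2, 3))
  for (ch in 1:3) {
    od <- deconvolve_stain(white, "H-DAB", channel = ch, output = "od")
    expect_lt(max(abs(od)), 1e-3)
  }
  # forward-compose a pixel carrying OD 1 of exactly one real stain,
  # invert (the residual vector is not representable: negative channels)
  M <- stain_vectors("H-DAB")
  for (s in 1:2) {
    od_true <- c(0, 0, 0); od_true[s] <- 1
    I <- 256 * 10^(-(od_true %*% M)) - 1
    px <- array(rep(pmin(pmax(I, 0), 255), each = 1), c(1, 1, 3))
    got <- vapply(1:3, function(ch)
      deconvolve_stain(px, "H-DAB", channel = ch, output = "od")[1, 1],
      numeric(1))
    expect_equal(got, od_true, tolerance = 1e-6)
  }
  # gray pixel: equal OD across RGB channels before unmixing
  g <- array(120, c(1, 1, 3))
  od_rgb <- -log10((120 + 1) / 256)
  expect_equal(rep(od_rgb, 3),
               as.numeric(-log10((g[1, 1, ] + 1) / 256)))
  # degenerate basis rejected
  bad <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_error(stain_vectors("custom", custom = bad), "independent")
})

test_that("binarize thresholds correctly, including Otsu separation", {
  z <- matrix(0, 10, 10)
  expect_false(any(binarize(z, 1)))
  expect_true(all(binarize(z, 0)))
  bi <- matrix(c(40, 200), 20, 20)
  m <- binarize(bi, "otsu")
  th <- attr(m, "threshold")
  expect_gt(th, 40)
  expect_lt(th, 200)
  expect_equal(sum(m), sum(bi >= th))
})

test_that("skeleton graph recovers line and junction geometry", {
  sk <- skeletonize(line_mask(50))
  expect_equal(length(sk$edges), 1)
  expect_equal(sk$total_length_px, 49)
  expect_equal(sk$n_endpoints, 2L)
  expect_equal(sk$n_branchpoints, 0L)

  skp <- skeletonize(plus_mask(21))
  expect_equal(skp$n_endpoints, 4L)
  expect_equal(skp$n_branchpoints, 1L)

  ske <- skeletonize(matrix(FALSE, 70, 70))
  expect_equal(ske$total_length_px, 0)
  expect_equal(length(ske$edges), 0)
})

test_that("fiber metrics normalize by total length and flag empties", {
  fm <- fiber_metrics(skeletonize(line_mask(50)))
  expect_equal(fm$norm_endpoints, 2 / 49)
  expect_equal(fm$norm_branchpoints, 0)

  two <- matrix(FALSE, 40, 70)
  two[10, 6:31] <- TRUE   # 26 px -> length 25
  two[30, 6:31] <- TRUE
  fm2 <- fiber_metrics(skeletonize(two))
  expect_equal(fm2$avg_fiber_length_px, 25)
  expect_equal(fm2$total_length_px, 50)

  fme <- fiber_metrics(skeletonize(matrix(FALSE, 70, 70)))
  expect_true(is.na(fme$norm_endpoints))
  expect_true(is.na(fme$norm_branchpoints))
  expect_true(is.na(fme$avg_fiber_length_px))
})

test_that("curvature matches chord geometry on straight and circular paths", {
  sk <- skeletonize(line_mask(50))
  for (w in c(10, 20)) expect_equal(curvature(sk, w), 0)

  # circle radius 100: chords of arc w turn by 2 asin(w / 2r)
  skc <- skeletonize(circle_mask(100))
  expect_equal(length(skc$edges), 1)   # one closed loop
  expect_equal(curvature(skc, 10), 2 * asin(10 / 200) * 180 / pi,
               tolerance = 0.10)
  expect_equal(curvature(skc, 20), 2 * asin(20 / 200) * 180 / pi,
               tolerance = 0.10)

  # 30-px fiber is ineligible at window 40
  expect_true(is.na(curvature(skeletonize(line_mask(30)), 40)))
})

test_that("hdm is the saturated-pixel fraction", {
  expect_equal(hdm(matrix(255, 5, 5)), 1)
  expect_equal(hdm(matrix(0, 5, 5)), 0)
  half <- matrix(c(255, 0), 10, 10)
  expect_equal(hdm(half, 128), 0.5)
  expect_equal(hdm(half, 0), 1)
})

test_that("gap analysis finds maximal inscribed circles", {
  expect_equal(gap_analysis(matrix(TRUE, 30, 30))$mean_gap_area_px2, 0)

  # foreground enclosing one empty disk of radius 20
  one <- holes_mask(101, 101, rbind(c(51, 51)), 20)
  ga <- gap_analysis(one)
  expect_equal(nrow(ga$gaps), 1)
  expect_equal(ga$gaps$area_px2[1], pi * 20^2, tolerance = 0.05)

  # two identical circular holes: two equal-area gaps by symmetry
  two <- holes_mask(60, 120, rbind(c(30, 30), c(30, 90)), 10)
  g2 <- gap_analysis(two)
  expect_equal(nrow(g2$gaps), 2)
  expect_equal(g2$gaps$area_px2[1], g2$gaps$area_px2[2])
  expect_equal(g2$mean_gap_area_px2, g2$gaps$area_px2[1])

  # square holes additionally seed corner circles; the two largest are
  # still the equal inscribed circles of the two holes
  sq <- matrix(TRUE, 60, 120)
  sq[21:40, 21:40] <- FALSE
  sq[21:40, 81:100] <- FALSE
  gs <- gap_analysis(sq)
  top <- sort(gs$gaps$area_px2, decreasing = TRUE)[1:2]
  expect_equal(top[1], top[2])
})

test_that("lacunarity matches gliding-box enumeration", {
  expect_equal(lacunarity(matrix(TRUE, 16, 16))$mean, 1)
  single <- matrix(FALSE, 4, 4); single[2, 2] <- TRUE
  expect_equal(lacunarity(single, box_sizes = 1)$mean, 16)
  expect_equal(lacunarity(checkerboard(8), box_sizes = 2)$mean, 1)
  expect_true(is.na(lacunarity(matrix(FALSE, 16, 16))$mean))

  # oracle equivalence on small random masks, several sizes
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(runif(16 * 16) < 0.4, 16, 16)
    if (!any(m)) next
    for (r in c(1, 2, 4)) {
      expect_equal(unname(lacunarity(m, box_sizes = r)$lambda[1]),
                   brute_lacunarity(m, r))
    }
  }
})

test_that("box-counting dimension hits the analytic values", {
  expect_equal(box_counting_fd(matrix(TRUE, 128, 128)), 2, tolerance = 0.025)
  ln <- matrix(FALSE, 128, 128); ln[64, ] <- TRUE
  expect_equal(box_counting_fd(ln), 1, tolerance = 0.05)
  expect_equal(box_counting_fd(sierpinski_mask(6)), log(3) / log(2),
               tolerance = 0.032)
  expect_true(is.na(box_counting_fd(matrix(FALSE, 64, 64))))
})

test_that("the assembled panel derives thickness from HDM and length", {
  # direct arithmetic: thickness = hdm * area / total_length
  expect_equal(0.1 * 10000 / 500, 2.0)

  bar <- matrix(FALSE, 20, 110); bar[9:11, 6:105] <- TRUE
  met <- ecm_metrics(mask = bar)
  expect_equal(met$fiber_thickness_px, 3, tolerance = 0.10)
  expect_equal(met$hdm_fraction, mean(bar))   # mask-only fallback
  expect_equal(met$fiber_thickness_px,
               met$hdm_fraction * length(bar) / met$total_length_px)

  empty <- ecm_metrics(mask = matrix(FALSE, 70, 70))
  expect_equal(empty$total_length_px, 0)
  expect_true(is.na(empty$fiber_thickness_px))
  expect_true(is.na(empty$lacunarity))
  expect_true(is.na(empty$bcfd))
})

test_that("metrics are robust to 90-degree rotation", {
  # three separated clean arcs (no junctions, no thinning ambiguity) on
  # a dyadic canvas, so box grids map onto box grids under rotation
  arcs <- matrix(FALSE, 256, 256)
  for (k in 1:3) {
    pts <- circle_pts(20 + 15 * k, cy = 128, cx = 128)
    arc <- pts[seq_len(floor(nrow(pts) / 3)), ]
    arcs[arc] <- TRUE
  }
  rot <- t(arcs)[ncol(arcs):1, ]
  m1 <- ecm_metrics(mask = arcs)
  m2 <- ecm_metrics(mask = rot)
  expect_equal(m1$total_length_px, m2$total_length_px)
  expect_equal(m1$n_branchpoints, m2$n_branchpoints)
  expect_equal(m1$n_endpoints, m2$n_endpoints)
  for (f in c("curvature10", "bcfd", "lacunarity")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 0.02)
  }
})

test_that("fiber thickness responds linearly to dilation", {
  # separated straight fibers so dilation cannot merge them; raster
  # dilation of a 1-px line yields odd widths, so compare 3 vs 7
  thin <- matrix(FALSE, 120, 120)
  thin[c(20, 60, 100), 11:110] <- TRUE
  dilate_to <- function(center, t) {
    edt <- as.matrix(EBImage::distmap((!center) * 1))
    center | edt <= (t - 1) / 2
  }
  m3 <- ecm_metrics(mask = dilate_to(thin, 3))
  m7 <- ecm_metrics(mask = dilate_to(thin, 7))
  expect_equal(m7$fiber_thickness_px / m3$fiber_thickness_px, 7 / 3,
               tolerance = 0.10)
  expect_equal(m3$n_branchpoints, m7$n_branchpoints)
  expect_equal(m3$n_endpoints, m7$n_endpoints)
})

test_that("holes and fibers move gap area and length monotonically", {
  base <- holes_mask(80, 80, rbind(c(25, 25)), 10)
  more <- holes_mask(80, 80, rbind(c(25, 25), c(55, 55)), 10)
  expect_gte(gap_analysis(more)$mean_gap_area_px2 * nrow(gap_analysis(more)$gaps),
             gap_analysis(base)$mean_gap_area_px2 * nrow(gap_analysis(base)$gaps))

  one <- line_mask(40, 80, 80, row = 20)
  two <- one; two[60, 11:50] <- TRUE
  expect_gt(skeletonize(two)$total_length_px,
            skeletonize(one)$total_length_px)
})

test_that("a directory of images produces one stable row per image", {
  d <- withr::local_tempdir()
  for (s in 1:2) {
    fi <- simulate_fiber_image(5, 0.05, seed = s, size = c(96, 96))
    write_image_png(fi$image, file.path(d, sprintf("img%d.png", s)))
  }
  res <- metrics_for_images(d)
  expect_equal(nrow(res), 2)
  expect_true(all(c("image", "total_length_px", "hdm_fraction",
                    "haralick_contrast") %in% names(res)))
})
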