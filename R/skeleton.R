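## Fiber-network skeleton: Zhang-Suen thinning to a 1-px centerline,
## then tracing into a graph of endpoints/branchpoints connected by
## ordered pixel paths. Path step lengths are 1 for axial moves and
## sqrt(2) for diagonal moves.

shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# 8-neighborhood in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
.zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Thin a binary mask to a 1-pixel-wide skeleton
#'
#' Zhang-Suen iterative thinning: the classic two-subiteration medial
#' axis algorithm, applied until no pixel changes.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape, 1-px-wide centerlines.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- lapply(.zs_offsets, function(o) shift_mat(m, o[1], o[2]))
      B <- Reduce(`+`, nb)
      # A = number of 0 -> 1 transitions in the cyclic sequence P2..P9,P2
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in seq_along(nb)) {
        j <- if (i == length(nb)) 1L else i + 1L
        A <- A + (nb[[i]] == 0L & nb[[j]] == 1L)
      }
      if (phase == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]]  # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]]  # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]]  # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]]  # P2*P6*P8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Extract the fiber network graph from a binary mask
#'
#' Thins the mask to a 1-px skeleton, classifies skeleton pixels by their
#' 8-neighborhood degree (1 = endpoint, >= 3 = branch pixel), and traces
#' the ordered pixel paths between node pixels. Adjacent branch pixels
#' are merged into a single branchpoint for counting. Connected
#' components with no node pixels (closed loops) become a single
#' closed-path edge. Isolated single pixels are dropped.
#'
#' @param mask logical matrix (a raw fiber mask; it is thinned first) or
#'   an already 1-px skeleton.
#' @return An object of class `skeleton_graph`: a list with `nodes`
#'   (data.frame `y`, `x`, `type`), `edges` (list of n x 2 path matrices,
#'   columns y, x), `total_length_px`, `n_branchpoints`, `n_endpoints`.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  sk <- thin_mask(mask)
  nr <- nrow(sk); nc <- ncol(sk)
  ski <- sk * 1L
  deg <- Reduce(`+`, lapply(.zs_offsets, function(o) shift_mat(ski, o[1], o[2])))
  deg[!sk] <- -1L

  # drop isolated pixels
  sk[deg == 0L] <- FALSE
  deg[deg == 0L] <- -1L

  if (!any(sk)) {
    return(structure(list(
      nodes = data.frame(y = integer(), x = integer(), type = character()),
      edges = list(), total_length_px = 0,
      n_branchpoints = 0L, n_endpoints = 0L), class = "skeleton_graph"))
  }

  is_node <- sk & (deg == 1L | deg >= 3L)
  ends <- which(sk & deg == 1L)
  branch_px <- sk & deg >= 3L
  n_branch <- if (any(branch_px))
    max(EBImage::bwlabel(branch_px * 1)) else 0L

  idx <- function(y, x) (x - 1L) * nr + y
  neighbors <- function(y, x) {
    ys <- y + c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
    xs <- x + c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
    ok <- ys >= 1L & ys <= nr & xs >= 1L & xs <= nc
    cbind(ys[ok], xs[ok])[sk[cbind(ys[ok], xs[ok])], , drop = FALSE]
  }

  visited_step <- new.env(hash = TRUE)   # directed first-steps already traced
  step_key <- function(a, b) paste(idx(a[1], a[2]), idx(b[1], b[2]))

  edges <- list()
  node_idx <- which(is_node)
  node_yx <- cbind((node_idx - 1L) %% nr + 1L, (node_idx - 1L) %/% nr + 1L)

  trace_from <- function(start, first) {
    # walk from a node pixel `start` through degree-2 pixels beginning at
    # `first`, until another node pixel (or dead end) is reached
    path <- rbind(start, first)
    prev <- start; cur <- first
    while (!is_node[cur[1], cur[2]]) {
      nb <- neighbors(cur[1], cur[2])
      nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nb) == 0) break                       # dead end
      nxt <- nb[1, ]
      path <- rbind(path, nxt)
      prev <- cur; cur <- nxt
      if (nrow(path) > nr * nc) stop("skeleton tracing failed to terminate")
    }
    path
  }

  for (k in seq_len(nrow(node_yx))) {
    a <- node_yx[k, ]
    for (nbk in seq_len(nrow(neighbors(a[1], a[2])))) {
      b <- neighbors(a[1], a[2])[nbk, ]
      kf <- step_key(a, b)
      if (!is.null(visited_step[[kf]])) next
      path <- trace_from(a, b)
      visited_step[[kf]] <- TRUE
      last2 <- path[nrow(path), ]; last1 <- path[nrow(path) - 1L, ]
      visited_step[[step_key(last2, last1)]] <- TRUE
      # skip pure node-to-adjacent-node hops inside a merged branch cluster
      if (nrow(path) == 2 && branch_px[a[1], a[2]] && branch_px[b[1], b[2]])
        next
      edges[[length(edges) + 1L]] <- unname(path)
    }
  }

  # closed loops: remaining degree-2 pixels never visited
  on_edge <- new.env(hash = TRUE)
  for (e in edges) for (r in seq_len(nrow(e)))
    on_edge[[as.character(idx(e[r, 1], e[r, 2]))]] <- TRUE
  deg2 <- which(sk & deg == 2L)
  for (p in deg2) {
    if (!is.null(on_edge[[as.character(p)]])) next
    y0 <- (p - 1L) %% nr + 1L; x0 <- (p - 1L) %/% nr + 1L
    nb <- neighbors(y0, x0)
    if (nrow(nb) == 0) next
    path <- trace_loop(c(y0, x0), nb[1, ], sk, nr, nc)
    for (r in seq_len(nrow(path)))
      on_edge[[as.character(idx(path[r, 1], path[r, 2]))]] <- TRUE
    edges[[length(edges) + 1L]] <- path
  }

  total <- sum(vapply(edges, path_length, numeric(1)))
  nodes <- data.frame(
    y = node_yx[, 1], x = node_yx[, 2],
    type = ifelse(deg[node_idx] == 1L, "endpoint", "branchpoint"),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, total_length_px = total,
                 n_branchpoints = as.integer(n_branch),
                 n_endpoints = length(ends)),
            class = "skeleton_graph")
}

# trace a closed loop of degree-2 pixels back to its start
trace_loop <- function(start, first, sk, nr, nc) {
  path <- rbind(start, first)
  prev <- start; cur <- first
  repeat {
    ys <- cur[1] + c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
    xs <- cur[2] + c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
    ok <- ys >= 1L & ys <= nr & xs >= 1L & xs <= nc
    nb <- cbind(ys[ok], xs[ok])
    nb <- nb[sk[nb], , drop = FALSE]
    nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
    if (nrow(nb) == 0) break
    nxt <- nb[1, ]
    if (nxt[1] == start[1] && nxt[2] == start[2]) {
      path <- rbind(path, nxt)   # close the loop
      break
    }
    path <- rbind(path, nxt)
    prev <- cur; cur <- nxt
    if (nrow(path) > nr * nc) break
  }
  unname(path)
}

path_length <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- diff(path)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", length(x$edges), "edges,",
      x$n_branchpoints, "branchpoints,", x$n_endpoints, "endpoints,",
      "total length", round(x$total_length_px, 2), "px\n")
  invisible(x)
}

#' Fiber counts and length metrics from a skeleton graph
#'
#' Branch and endpoint counts are normalized by dividing by the total
#' skeleton length; average fiber length is total length over the number
#' of edges. On an empty skeleton the normalized metrics are undefined
#' and returned as `NA` (never coerced to 0) so that downstream screens
#' can drop them explicitly.
#'
#' @param sk a [skeletonize()] result.
#' @return One-row data.frame: `total_length_px`, `n_branchpoints`,
#'   `n_endpoints`, `norm_branchpoints`, `norm_endpoints`,
#'   `avg_fiber_length_px`.
#' @export
fiber_metrics <- function(sk) {
  stopifnot(inherits(sk, "skeleton_graph"))
  L <- sk$total_length_px
  if (L > 0) {
    data.frame(total_length_px = L,
               n_branchpoints = sk$n_branchpoints,
               n_endpoints = sk$n_endpoints,
               norm_branchpoints = sk$n_branchpoints / L,
               norm_endpoints = sk$n_endpoints / L,
               avg_fiber_length_px = L / length(sk$edges))
  } else {
    data.frame(total_length_px = 0, n_branchpoints = 0L, n_endpoints = 0L,
               norm_branchpoints = NA_real_, norm_endpoints = NA_real_,
               avg_fiber_length_px = NA_real_)
  }
}

#' Mean fiber curvature at a fixed chord window
#'
#' Each edge path is resampled at equal arc-length spacing `window_px`
#' (linear interpolation along the pixel path); the metric is the mean
#' absolute angle, in degrees, between successive chords, pooled over all
#' edges whose path length is at least twice the window. With no eligible
#' edge the metric is undefined (`NA`).
#'
#' @param sk a [skeletonize()] result.
#' @param window_px chord spacing in pixels (conventionally 10-40).
#' @return Mean absolute inter-chord angle in degrees, or `NA`.
#' @export
curvature <- function(sk, window_px) {
  stopifnot(inherits(sk, "skeleton_graph"), window_px > 0)
  angles <- numeric(0)
  for (e in sk$edges) {
    if (nrow(e) < 2) next
    d <- diff(e)
    seg <- sqrt(d[, 1]^2 + d[, 2]^2)
    arc <- c(0, cumsum(seg))
    L <- arc[length(arc)]
    if (L < 2 * window_px) next
    s <- seq(0, L, by = window_px)
    py <- approx_at(arc, e[, 1], s)
    px <- approx_at(arc, e[, 2], s)
    ch <- cbind(diff(py), diff(px))
    if (nrow(ch) < 2) next
    for (i in seq_len(nrow(ch) - 1)) {
      a <- ch[i, ]; b <- ch[i + 1, ]
      cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
  }
  if (length(angles) == 0) return(NA_real_)
  mean(angles)
}

approx_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}
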