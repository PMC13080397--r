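# Geometric fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (full enumeration) and never call
# the implementation they check.

line_mask <- function(len = 50, nr = 60, nc = 60, row = 30, col0 = 6) {
  m <- matrix(FALSE, nr, nc)
  m[row, col0:(col0 + len - 1)] <- TRUE
  m
}

plus_mask <- function(arm = 21, n = 41) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1) %/% 2
  h <- (arm - 1) %/% 2
  m[c0, (c0 - h):(c0 + h)] <- TRUE
  m[(c0 - h):(c0 + h), c0] <- TRUE
  m
}

# Bresenham midpoint circle: pixel set ordered by angle (clean 1-px ring)
circle_pts <- function(r = 100, cy = r + 11, cx = r + 11) {
  x <- 0; y <- r; d <- 1 - r; pts <- NULL
  while (x <= y) {
    pts <- rbind(pts, cbind(c(x, y, y, x, -x, -y, -y, -x),
                            c(y, x, -x, -y, -y, -x, x, y)))
    if (d < 0) d <- d + 2 * x + 3 else { d <- d + 2 * (x - y) + 5; y <- y - 1 }
    x <- x + 1
  }
  pts <- unique(pts)
  pts <- pts[order(atan2(pts[, 1], pts[, 2])), ]
  cbind(cy + pts[, 1], cx + pts[, 2])
}

circle_mask <- function(r = 100) {
  pts <- circle_pts(r)
  n <- 2 * r + 21
  m <- matrix(FALSE, n, n)
  m[pts] <- TRUE
  m
}

# a skeleton_graph holding one explicit path (bypasses thinning)
path_graph <- function(pts) {
  structure(list(
    nodes = data.frame(y = integer(), x = integer(), type = character()),
    edges = list(unname(pts)),
    total_length_px = sum(sqrt(rowSums(diff(pts)^2))),
    n_branchpoints = 0L, n_endpoints = 2L), class = "skeleton_graph")
}

sierpinski_mask <- function(depth = 6) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, z), cbind(m, m))
  }
  m
}

checkerboard <- function(n = 8) {
  outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 1)
}

# foreground everywhere except circular holes
holes_mask <- function(nr, nc, centers, radius) {
  m <- matrix(TRUE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    m[(rows - centers[k, 1])^2 + (cols - centers[k, 2])^2 <= radius^2] <- FALSE
  }
  m
}

## ---- brute-force oracles ----

# gliding-box lacunarity by direct loop over every box position
brute_lacunarity <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  ms <- c()
  for (y in 1:(nr - r + 1)) for (x in 1:(nc - r + 1)) {
    ms <- c(ms, sum(mask[y:(y + r - 1), x:(x + r - 1)]))
  }
  mean(ms^2) / mean(ms)^2
}

# GLCM statistics by direct enumeration of all pixel pairs at an offset
brute_glcm_stats <- function(img, offset, levels, symmetric = TRUE) {
  rng <- range(img)
  q <- if (diff(rng) == 0) matrix(1L, nrow(img), ncol(img)) else
    pmin(floor((img - rng[1]) / diff(rng) * levels) + 1L, levels)
  pairs <- NULL
  nr <- nrow(img); nc <- ncol(img)
  for (y in 1:nr) for (x in 1:nc) {
    y2 <- y + offset[1]; x2 <- x + offset[2]
    if (y2 >= 1 && y2 <= nr && x2 >= 1 && x2 <= nc)
      pairs <- rbind(pairs, c(q[y, x], q[y2, x2]))
  }
  if (symmetric) pairs <- rbind(pairs, pairs[, 2:1])
  P <- matrix(0, levels, levels)
  for (k in seq_len(nrow(pairs))) {
    P[pairs[k, 1], pairs[k, 2]] <- P[pairs[k, 1], pairs[k, 2]] + 1
  }
  P <- P / sum(P)
  i <- matrix(1:levels, levels, levels); j <- t(i)
  nz <- P > 0
  list(contrast = sum(P * (i - j)^2), energy = sum(P^2),
       homogeneity = sum(P / (1 + abs(i - j))),
       entropy = -sum(P[nz] * log2(P[nz])))
}

# exact permutation p-value of |spearman rho| by full enumeration (n <= 7)
perm_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  r_obs <- cor(rank(x), rank(y))
  rs <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in 1:n) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# exact hypergeometric upper tail by combinatorial enumeration
brute_hypergeom_upper <- function(N, K, n, k_obs) {
  ks <- max(0, n + K - N):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k_obs])
}

# ssGSEA running sum evaluated step by step (independent of the package)
brute_ssgsea <- function(x, set, alpha = 0.25) {
  n <- length(x)
  ord <- order(-x, names(x))
  inset <- names(x)[ord] %in% set
  rank_val <- n:1
  w <- rank_val^alpha
  p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
  p_out <- cumsum(!inset) / (n - sum(inset))
  sum(p_in - p_out) / n
}

default_sigs <- function() synthetic_signatures(n_genes = 120, set_size = 8)
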