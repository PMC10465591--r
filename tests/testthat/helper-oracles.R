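# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written as plain loops against the definitions, on
# purpose: none of it shares code with the package internals.

# distance from point p to segment [a, b]
oracle_pt_seg <- function(p, a, b) {
  d <- b - a
  t2 <- sum(d^2)
  t <- if (t2 == 0) 0 else max(0, min(1, sum((p - a) * d) / t2))
  sqrt(sum((p - (a + t * d))^2))
}

# minimum distance from point p to a polyline given by its vertex matrix
oracle_pt_polyline <- function(p, verts) {
  best <- Inf
  for (j in seq_len(nrow(verts) - 1L))
    best <- min(best, oracle_pt_seg(p, verts[j, ], verts[j + 1L, ]))
  best
}

# n points spread uniformly in arc length along a polyline
oracle_dense_points <- function(verts, n) {
  seg <- sqrt(rowSums((verts[-1L, , drop = FALSE] -
                         verts[-nrow(verts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- seq(0, cs[length(cs)], length.out = n)
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    j <- max(which(cs <= s[i] + 1e-12))
    j <- min(j, length(cs) - 1L)
    t <- (s[i] - cs[j]) / seg[j]
    out[i, ] <- verts[j, ] + t * (verts[j + 1L, ] - verts[j, ])
  }
  out
}

# symmetric mean curve distance by dense vertex sampling of both curves
oracle_smcd_dense <- function(va, vb, n = 10000L) {
  pa <- oracle_dense_points(va, n)
  pb <- oracle_dense_points(vb, n)
  min_to <- function(p, q) {
    qq <- rowSums(q^2)
    out <- numeric(nrow(p))
    for (s in seq(1L, nrow(p), by = 500L)) {
      e <- min(s + 499L, nrow(p))
      blk <- p[s:e, , drop = FALSE]
      d2 <- outer(rowSums(blk^2), qq, `+`) - 2 * tcrossprod(blk, q)
      out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
    }
    out
  }
  (mean(min_to(pa, pb)) + mean(min_to(pb, pa))) / 2
}

# exhaustive voxel-centre containment test for a tube
oracle_tube_mask <- function(verts, shape, spacing, origin, radius) {
  out <- array(FALSE, dim = shape)
  for (i in 0:(shape[1] - 1)) for (j in 0:(shape[2] - 1))
    for (k in 0:(shape[3] - 1)) {
      ctr <- origin + c(i, j, k) * spacing
      out[i + 1, j + 1, k + 1] <- oracle_pt_polyline(ctr, verts) <= radius
    }
  out
}

# surface voxels (6-connectivity, out-of-bounds counts as background)
oracle_surface <- function(vals) {
  d <- dim(vals)
  keep <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!vals[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_surf <- FALSE
    for (r in 1:6) {
      q <- nb[r, ]
      if (any(q < 1) || any(q > d) || !vals[q[1], q[2], q[3]]) {
        is_surf <- TRUE; break
      }
    }
    if (is_surf) keep <- rbind(keep, c(i, j, k) - 1)
  }
  keep
}

# all-pairs average symmetric surface distance
oracle_assd <- function(vals_a, vals_b, spacing, origin) {
  sa <- sweep(oracle_surface(vals_a) %*% diag(spacing), 2, origin, `+`)
  sb <- sweep(oracle_surface(vals_b) %*% diag(spacing), 2, origin, `+`)
  da <- apply(sa, 1, function(p) min(sqrt(colSums((t(sb) - p)^2))))
  db <- apply(sb, 1, function(p) min(sqrt(colSums((t(sa) - p)^2))))
  (sum(da) + sum(db)) / (length(da) + length(db))
}

# random non-degenerate polyline with n vertices
rand_polyline <- function(n, scale = 10) {
  steps <- matrix(stats::runif(3 * (n - 1), 0.5, 2), n - 1, 3) *
    sign(matrix(stats::rnorm(3 * (n - 1)), n - 1, 3))
  rbind(0, apply(steps, 2, cumsum)) * scale / n
}

# rigid rotation + translation applied to a point matrix
rigid_transform <- function(pts, angles = c(0.4, -0.3, 0.7),
                            shift = c(5, -3, 2)) {
  rx <- rbind(c(1, 0, 0),
              c(0, cos(angles[1]), -sin(angles[1])),
              c(0, sin(angles[1]), cos(angles[1])))
  ry <- rbind(c(cos(angles[2]), 0, sin(angles[2])),
              c(0, 1, 0),
              c(-sin(angles[2]), 0, cos(angles[2])))
  rz <- rbind(c(cos(angles[3]), -sin(angles[3]), 0),
              c(sin(angles[3]), cos(angles[3]), 0),
              c(0, 0, 1))
  sweep(pts %*% t(rz %*% ry %*% rx), 2, shift, `+`)
}
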