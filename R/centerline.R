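#' Extract centerlines from a binary mask
#'
#' Utility for turning a tubular mask back into ordered centerline curves,
#' one per 26-connected component.  Within each component the foreground
#' voxel graph (26-neighbourhood, edges weighted by physical length and
#' penalised away from the medial axis using an iterative-erosion depth
#' map) is traversed along its longest geodesic, so the returned polyline
#' runs end to end through the most central voxels.  Every returned point
#' is a foreground voxel centre; a light moving-average smoothing can be
#' applied to suppress voxel-level zigzag.
#'
#' This is plumbing for round-trip checks of tube voxelization, not a
#' general-purpose skeletonisation of arbitrary shapes.
#'
#' @param mask a non-empty [voxel_mask()].
#' @param smooth half-width (in points) of an optional moving-average
#'   smoothing of the recovered polyline; the default 0 returns raw voxel
#'   centres, any positive value moves interior points off them.
#' @return A list of [canal_curve()] objects, one per component, in
#'   decreasing order of component size.
#' @export
centerline_from_mask <- function(mask, smooth = 0L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$values)) stop("mask is empty: no centerline to extract")
  d <- dim(mask$values)
  fg <- which(mask$values, arr.ind = TRUE)  # 1-based
  nfg <- nrow(fg)
  id <- array(0L, dim = d)
  id[fg] <- seq_len(nfg)

  depth <- erosion_depth(mask$values)

  # 26-neighbourhood edges between foreground voxels
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one direction of each pair to avoid duplicate edges
  keep <- offs[, 1L] > 0 |
    (offs[, 1L] == 0 & offs[, 2L] > 0) |
    (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0)
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0); to <- integer(0); elen <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(fg, 2L, offs[r, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nbid <- integer(nfg)
    nbid[ok] <- id[nb[ok, , drop = FALSE]]
    ok <- ok & nbid > 0L
    if (!any(ok)) next
    from <- c(from, which(ok))
    to <- c(to, nbid[ok])
    elen <- c(elen, rep(sqrt(sum((offs[r, ] * mask$spacing)^2)), sum(ok)))
  }
  g <- igraph::make_graph(rbind(from, to), n = nfg, directed = FALSE)
  comp <- igraph::components(g)

  dmax <- max(depth[fg])
  # central voxels get cheap edges; +1 keeps weights strictly positive
  wcost <- (dmax - depth[fg]) + 1
  weights <- elen * (wcost[from] + wcost[to]) / 2

  ord <- order(comp$csize, decreasing = TRUE)
  curves <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ord[ci])
    if (length(members) == 1L) {
      pt <- voxel_centers(mask, fg[members, , drop = FALSE] - 1L)
      curves[[ci]] <- canal_curve(rbind(pt, pt + mask$spacing * 1e-6))
      next
    }
    sub_edges <- which(comp$membership[from] == ord[ci])
    # geodesic double sweep (by physical length) to find the two ends
    glen <- igraph::make_graph(rbind(from[sub_edges], to[sub_edges]),
                               n = nfg, directed = FALSE)
    d0 <- igraph::distances(glen, v = members[1L], to = members,
                            weights = elen[sub_edges])
    e1 <- members[which.max(d0)]
    d1 <- igraph::distances(glen, v = e1, to = members,
                            weights = elen[sub_edges])
    e2 <- members[which.max(d1)]
    # centrality-weighted shortest path between the two ends
    path <- igraph::shortest_paths(glen, from = e1, to = e2,
                                   weights = weights[sub_edges])$vpath[[1L]]
    idx0 <- fg[as.integer(path), , drop = FALSE] - 1L
    pts <- voxel_centers(mask, idx0)
    if (smooth > 0L && nrow(pts) > 2L * smooth + 2L)
      pts <- smooth_polyline(pts, smooth)
    curves[[ci]] <- canal_curve(pts)
  }
  curves
}

# integer erosion depth: number of 6-connected peeling iterations a voxel
# survives (1 on the surface); cheap stand-in for a distance transform,
# used only to bias paths toward the medial axis
erosion_depth <- function(values) {
  d <- dim(values)
  depth <- array(0L, dim = d)
  cur <- values
  lvl <- 0L
  while (any(cur)) {
    lvl <- lvl + 1L
    depth[cur] <- lvl
    interior <- cur
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      out <- array(FALSE, dim = d)
      n <- d[ax]
      src <- dst <- lapply(d, seq_len)
      if (by > 0) { dst[[ax]] <- seq_len(n - 1L); src[[ax]] <- seq_len(n - 1L) + 1L }
      else        { dst[[ax]] <- seq_len(n - 1L) + 1L; src[[ax]] <- seq_len(n - 1L) }
      out[dst[[1L]], dst[[2L]], dst[[3L]]] <- cur[src[[1L]], src[[2L]], src[[3L]]]
      interior <- interior & out
    }
    cur <- interior
  }
  depth
}

# moving-average smoothing with fixed endpoints
smooth_polyline <- function(pts, half) {
  n <- nrow(pts)
  out <- pts
  for (i in seq_len(n)) {
    w <- min(half, i - 1L, n - i)
    if (w > 0L) out[i, ] <- colMeans(pts[(i - w):(i + w), , drop = FALSE])
  }
  # drop points that collapsed onto each other
  keep <- c(TRUE, rowSums((out[-1L, , drop = FALSE] -
                             out[-n, , drop = FALSE])^2) > 1e-20)
  out[keep, , drop = FALSE]
}
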