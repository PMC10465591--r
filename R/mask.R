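#' Binary voxel mask
#'
#' A 3D binary occupancy grid with anisotropic spacing.  World coordinates
#' follow the voxel-centre convention with 0-based indices: the centre of
#' voxel (i, j, k) is at `origin + c(i, j, k) * spacing`.
#'
#' @param values logical (or 0/1) 3D array of occupancy.
#' @param spacing numeric length-3, mm per voxel along each axis, all > 0.
#' @param origin numeric length-3, world mm coordinate of the centre of
#'   voxel (0, 0, 0).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive lengths (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite 3D offset (mm)")
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  dim(values) <- unname(dim(values))
  dimnames(values) <- NULL
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

#' Empty grid template covering a set of curves
#'
#' Builds an all-background `voxel_mask` whose extent covers the bounding
#' box of the given curves plus a margin, for use as the `grid` argument of
#' [voxelize_tube()].
#'
#' @param curves a `canal_curve` or list of them.
#' @param spacing scalar or length-3 voxel spacing in mm.
#' @param margin extra extent beyond the bounding box on every side, mm.
#' @return A `voxel_mask` with no foreground.
#' @export
grid_for_curves <- function(curves, spacing, margin = 2) {
  if (inherits(curves, "canal_curve")) curves <- list(curves)
  pts <- do.call(rbind, lapply(curves, `[[`, "points"))
  spacing <- rep_len(as.numeric(spacing), 3L)
  lo <- apply(pts, 2L, min) - margin
  hi <- apply(pts, 2L, max) + margin
  shape <- pmax(ceiling((hi - lo) / spacing) + 1L, 1L)
  voxel_mask(array(FALSE, dim = shape), spacing = spacing, origin = lo)
}

# world coordinates of the centres of the given 0-based voxel index matrix
voxel_centers <- function(mask, idx0) {
  sweep(sweep(idx0, 2L, mask$spacing, `*`), 2L, mask$origin, `+`)
}

#' Voxelize a curve into a fixed-diameter tube
#'
#' Marks as foreground exactly those voxels of `grid` whose centres lie
#' within `radius` of the curve polyline (exact point-to-segment distance).
#' The default radius of 0.75 mm gives the 1.5 mm diameter tube used for
#' approximate canal segmentations.
#'
#' @param curve a [canal_curve()].
#' @param grid a `voxel_mask` template supplying shape/spacing/origin.
#' @param radius tube radius in mm, > 0.
#' @return A `voxel_mask` on the same grid.
#' @export
voxelize_tube <- function(curve, grid, radius = 0.75) {
  stopifnot(inherits(curve, "canal_curve"), inherits(grid, "voxel_mask"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive length (mm)")
  shape <- dim(grid$values)
  sp <- grid$spacing
  or <- grid$origin
  out <- array(FALSE, dim = shape)
  verts <- curve$points
  nseg <- nrow(verts) - 1L
  for (j in seq_len(nseg)) {
    a <- verts[j, ]; b <- verts[j + 1L, ]
    lo <- pmin(a, b) - radius
    hi <- pmax(a, b) + radius
    i0 <- pmax(floor((lo - or) / sp), 0)
    i1 <- pmin(ceiling((hi - or) / sp), shape - 1L)
    if (any(i1 < i0)) next
    ii <- seq.int(i0[1L], i1[1L]); jj <- seq.int(i0[2L], i1[2L])
    kk <- seq.int(i0[3L], i1[3L])
    idx0 <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    ctr <- voxel_centers(grid, idx0)
    d <- verts[j + 1L, ] - verts[j, ]
    w <- sweep(ctr, 2L, a)
    t <- pmin(pmax((w %*% d) / sum(d^2), 0), 1)
    dist2 <- rowSums((w - tcrossprod(as.numeric(t), d))^2)
    sel <- dist2 <= radius^2
    if (any(sel)) out[idx0[sel, , drop = FALSE] + 1L] <- TRUE
  }
  if (!any(out))
    stop("curve lies entirely outside the grid: tube mask is empty")
  voxel_mask(out, spacing = sp, origin = or)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop("masks are not on the same grid (shape/spacing/origin must match)")
}

#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint masks.  Both masks must live on the same grid.
#'
#' @param a,b `voxel_mask` objects on identical grids.
#' @return Numeric in \[0, 1\].
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  check_same_grid(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) stop("both masks are empty; DSC is undefined")
  2 * sum(a$values & b$values) / (na + nb)
}

# 0-based index matrix of surface voxels: foreground with at least one
# six-connected background or out-of-bounds neighbour
surface_voxels <- function(mask) {
  v <- mask$values
  d <- dim(v)
  interior <- array(TRUE, dim = d)
  shift_and <- function(arr, ax, by) {
    out <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- seq_len(n - by); src[[ax]] <- seq_len(n - by) + by }
    else        { dst[[ax]] <- seq_len(n + by) - by; src[[ax]] <- seq_len(n + by) }
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- arr[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_and(v, ax, by)
  surf <- v & !interior
  which(surf, arr.ind = TRUE) - 1L
}

# for each row of pa, distance in mm to the nearest row of pb (both world
# coordinate matrices); chunked BLAS-based computation
nearest_dist <- function(pa, pb, chunk = 2000L) {
  nb2 <- rowSums(pb^2)
  n <- nrow(pa)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- pa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), nb2, `+`) - 2 * tcrossprod(block, pb)
    # row minima via max.col (C level) rather than apply()
    j <- max.col(-d2, ties.method = "first")
    out[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), j)], 0))
  }
  out
}

# exact nearest-surface distances for surfaces living on one voxel grid:
# expanding-ring search in index space (a voxel is resolved once its best
# candidate cannot be beaten by any unscanned offset), with a brute-force
# fallback for the rare far-away remainder (e.g. truncated tube ends)
surface_dist_grid <- function(idxA, surfB, spacing, r_max = 4L) {
  m <- nrow(idxA)
  d <- dim(surfB)
  best <- rep(Inf, m)
  unresolved <- seq_len(m)
  min_sp <- min(spacing)
  for (r in 0:r_max) {
    if (!length(unresolved)) break
    ring <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
    ring <- ring[apply(abs(ring), 1L, max) == r, , drop = FALSE]
    dd_ring <- sqrt(colSums((t(ring) * spacing)^2))
    ord <- order(dd_ring)
    for (o in ord) {
      u <- unresolved[dd_ring[o] < best[unresolved]]
      if (!length(u)) next
      nb <- sweep(idxA[u, , drop = FALSE], 2L, ring[o, ], `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      if (!any(ok)) next
      hit <- ok
      hit[ok] <- surfB[nb[ok, , drop = FALSE]]
      best[u[hit]] <- pmin(best[u[hit]], dd_ring[o])
    }
    unresolved <- unresolved[best[unresolved] > (r + 1) * min_sp]
  }
  if (length(unresolved)) {
    pa <- sweep(sweep(idxA[unresolved, , drop = FALSE] - 1, 2L, spacing, `*`),
                2L, c(0, 0, 0), `+`)
    idxB <- which(surfB, arr.ind = TRUE)
    pb <- sweep(idxB - 1, 2L, spacing, `*`)
    best[unresolved] <- pmin(best[unresolved], nearest_dist(pa, pb))
  }
  best
}

#' Average symmetric surface distance (ASSD)
#'
#' Surface voxels are foreground voxels with at least one six-connected
#' background (or out-of-bounds) neighbour.  For every surface voxel centre
#' of each mask the Euclidean distance (mm, anisotropic spacing respected)
#' to the nearest surface voxel centre of the other mask is taken; ASSD is
#' the grand mean over both surfaces.
#'
#' @param a,b non-empty `voxel_mask` objects on identical grids.
#' @return Non-negative numeric scalar, mm; 0 iff the surfaces coincide.
#' @export
assd <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  check_same_grid(a, b)
  if (!any(a$values) || !any(b$values))
    stop("ASSD requires both masks to be non-empty")
  ia <- surface_voxels(a) + 1L
  ib <- surface_voxels(b) + 1L
  arr_a <- array(FALSE, dim = dim(a$values)); arr_a[ia] <- TRUE
  arr_b <- array(FALSE, dim = dim(b$values)); arr_b[ib] <- TRUE
  da <- surface_dist_grid(ia, arr_b, a$spacing)
  db <- surface_dist_grid(ib, arr_a, b$spacing)
  (sum(da) + sum(db)) / (nrow(ia) + nrow(ib))
}

#' Read a binary mask from a NIfTI-1 (or NRRD) volume
#'
#' Spacing is taken from the header; any non-zero voxel is foreground.  The
#' origin is kept at the header translation so world coordinates follow the
#' voxel-centre convention used throughout.
#'
#' @param path file path (`.nii`, `.nii.gz`; NRRD accepted read-only).
#' @return A `voxel_mask`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.array(img) != 0, dim = dim(img))
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  voxel_mask(vals, spacing = abs(spacing), origin = origin)
}

#' Write a binary mask as NIfTI-1
#' @param mask a `voxel_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  xf <- rbind(cbind(diag(mask$spacing), mask$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
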