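#' Canal centerline curve
#'
#' Constructs a `canal_curve`: the ordered 3D polyline of one mandibular
#' canal in one scan, in world millimetre coordinates.  By convention the
#' anterior (mental foramen) end comes first.  Consecutive duplicate points
#' are merged with a warning; a curve must retain at least two distinct
#' points and finite coordinates.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), ordered
#'   along the canal, anterior end first.
#' @param subject_id,scan_id opaque identifier strings.
#' @param side `"left"` or `"right"`, in the patient's anatomical frame.
#' @return An object of class `canal_curve`.
#' @examples
#' cv <- canal_curve(cbind(x = 0:3 * 3, y = 0, z = 0), "p1", "s1", "left")
#' arc_length(cv)
#' @export
canal_curve <- function(points, subject_id = "subject", scan_id = "scan",
                        side = c("left", "right")) {
  side <- match.arg(side)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must have exactly 3 columns (x, y, z in mm)")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("curve coordinates must be finite")
  if (nrow(points) >= 2L) {
    seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
    if (any(seg == 0)) {
      warning("merging duplicate consecutive control points")
      points <- points[c(TRUE, seg > 0), , drop = FALSE]
    }
  }
  if (nrow(points) < 2L)
    stop("a canal curve needs at least 2 distinct points")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(
    list(subject_id = as.character(subject_id),
         scan_id = as.character(scan_id),
         side = side,
         points = points),
    class = "canal_curve")
}

#' @export
print.canal_curve <- function(x, ...) {
  cat(sprintf("<canal_curve> subject %s, scan %s, %s side\n",
              x$subject_id, x$scan_id, x$side))
  cat(sprintf("  %d control points, arc length %.2f mm\n",
              nrow(x$points), arc_length(x)))
  invisible(x)
}

#' Total arc length of a curve in mm
#' @param curve a [canal_curve()].
#' @return Numeric scalar, mm.
#' @export
arc_length <- function(curve) {
  p <- curve$points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arc length at each vertex, starting at 0
cum_arc_length <- function(points) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# linear interpolation of the polyline at arc-length positions s
interp_at_arc <- function(points, s) {
  cs <- cum_arc_length(points)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  # index of segment containing each s
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx[idx >= length(cs)] <- length(cs) - 1L
  t <- (s - cs[idx]) / (cs[idx + 1L] - cs[idx])
  points[idx, , drop = FALSE] +
    t * (points[idx + 1L, , drop = FALSE] - points[idx, , drop = FALSE])
}

#' Resample a curve at uniform arc-length spacing
#'
#' Returns points on the input polyline at arc-length positions
#' 0, `step`, 2 `step`, ...; the final input endpoint is always included
#' (appended when the total length is not a multiple of `step`).
#'
#' @param curve a [canal_curve()].
#' @param step sampling interval in mm, > 0.
#' @return A `canal_curve` with the resampled points.
#' @export
resample_curve <- function(curve, step) {
  stopifnot(inherits(curve, "canal_curve"))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("'step' must be a single positive number (mm)")
  total <- arc_length(curve)
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9 * max(1, total)) s <- c(s, total)
  pts <- interp_at_arc(curve$points, s)
  canal_curve(pts, curve$subject_id, curve$scan_id, curve$side)
}

# minimum distance from each row of p (n x 3) to polyline given by verts
# (m x 3): exact point-to-segment, minimised over segments
point_polyline_distance <- function(p, verts) {
  a <- verts[-nrow(verts), , drop = FALSE]
  b <- verts[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  n <- nrow(p)
  m <- nrow(a)
  best <- rep(Inf, n)
  for (j in seq_len(m)) {
    w <- sweep(p, 2L, a[j, ])
    t <- pmin(pmax((w %*% d[j, ]) / len2[j], 0), 1)
    diff <- w - tcrossprod(as.numeric(t), d[j, ])
    best <- pmin(best, rowSums(diff^2))
  }
  sqrt(best)
}

#' Symmetric mean curve distance (SMCD)
#'
#' Average deviation between two canal centerlines: each curve is resampled
#' at uniform arc-length spacing, the mean exact point-to-polyline distance
#' to the other curve is taken in both directions, and the two directed
#' means are averaged.  Symmetric in its arguments and invariant under a
#' rigid transform applied to both curves.
#'
#' @param a,b [canal_curve()] objects.
#' @param step resampling interval in mm (default 0.5, finer than the 3 mm
#'   annotation interval so the result is resolution-stable).
#' @return Non-negative numeric scalar, mm.
#' @export
smcd <- function(a, b, step = 0.5) {
  stopifnot(inherits(a, "canal_curve"), inherits(b, "canal_curve"))
  pa <- resample_curve(a, step)$points
  pb <- resample_curve(b, step)$points
  d_ab <- mean(point_polyline_distance(pa, b$points))
  d_ba <- mean(point_polyline_distance(pb, a$points))
  (d_ab + d_ba) / 2
}
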