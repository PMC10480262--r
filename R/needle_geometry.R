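# Dense interpolated needle paths with arc-length maps.
#
# Each needle is represented by ~6000 points on an interpolating curve
# through its control points (tip followed by the dwells, tip-ward to
# inferior), together with the cumulative arc length from the tip.  The
# shared index between the point array and the arc-length array is what the
# dwell-shift operator uses to move dwells along the needle.

#' Build dense interpolated needle paths
#'
#' Fits a clamped interpolating cubic spline (composite Bezier-type curve)
#' through each needle's control polygon -- the tip control point followed by
#' the dwell positions -- parameterised by cumulative chord length, and
#' samples it densely.  The curve passes through the tip and every dwell, so
#' a zero-magnitude shift reproduces the nominal dwells exactly (to the
#' sampling resolution).  A needle with a single dwell is handled as the
#' straight tip-to-dwell segment extended 20 mm inferiorly along the same
#' direction so shifts have room to move.
#'
#' @param dwells a [dwell_set()].
#' @param n_points number of sampled points per needle (default 6000).
#' @return object of class `needle_paths`: a list with per-needle `points`
#'   (n x 3 matrices, mm) and `arclengths` (cumulative distance from the tip,
#'   mm, `arclengths[1] == 0`).
#' @export
build_needle_paths <- function(dwells, n_points = 6000) {
  stopifnot(inherits(dwells, "dwell_set"), n_points >= 2)
  paths <- vector("list", n_needles(dwells))
  for (i in seq_len(n_needles(dwells))) {
    ctrl <- rbind(dwells$tips[[i]], dwells$positions[[i]])
    # drop a duplicated first dwell when the tip coincides with it
    keep <- c(TRUE, sqrt(rowSums((ctrl[-1, , drop = FALSE] -
                                  ctrl[-nrow(ctrl), , drop = FALSE])^2)) > 1e-9)
    ctrl <- ctrl[keep, , drop = FALSE]
    if (nrow(ctrl) < 2L) {
      stop(sprintf(
        "build_needle_paths: needle %d control points are coincident; cannot form a curve", i))
    }
    if (nrow(ctrl) == 2L) {
      dirv <- ctrl[2, ] - ctrl[1, ]
      dirv <- dirv / sqrt(sum(dirv^2))
      ctrl <- rbind(ctrl, ctrl[2, ] + 20 * dirv)  # inferior extension, mm
    }
    chord <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
    tt <- seq(0, chord[length(chord)], length.out = n_points)
    pts <- vapply(1:3, function(d)
      stats::spline(chord, ctrl[, d], xout = tt, method = "natural")$y,
      numeric(length(tt)))
    seg <- sqrt(rowSums(diff(pts)^2))
    paths[[i]] <- list(points = pts, arclengths = c(0, cumsum(seg)))
  }
  structure(paths, class = "needle_paths")
}

#' Index of the path point nearest to a query point
#'
#' Exhaustive Euclidean nearest point; ties broken towards the lowest index
#' for determinism.
#'
#' @param path one element of a `needle_paths` object.
#' @param point length-3 numeric vector, mm.
#' @return integer index into `path$points`.
#' @export
nearest_path_index <- function(path, point) {
  if (is.null(path$points) || nrow(path$points) == 0L)
    stop("nearest_path_index: empty path")
  d2 <- (path$points[, 1] - point[1])^2 + (path$points[, 2] - point[2])^2 +
    (path$points[, 3] - point[3])^2
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

# Nearest index into a sorted arc-length array; lowest index on ties.
nearest_arclength_index <- function(arclengths, target) {
  n <- length(arclengths)
  k <- findInterval(target, arclengths)
  if (k <= 0L) return(1L)
  if (k >= n) return(n)
  lo <- target - arclengths[k]
  hi <- arclengths[k + 1L] - target
  if (lo <= hi) k else k + 1L
}

# Unit tangent of the path at index k (central difference).
path_tangent <- function(path, k) {
  n <- nrow(path$points)
  a <- max(1L, k - 1L); b <- min(n, k + 1L)
  v <- path$points[b, ] - path$points[a, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(0, 0, 1) else v / nv
}
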