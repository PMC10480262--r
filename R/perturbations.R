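# The six variable-parameter operators that turn a nominal plan into an
# uncertainty scenario:
#   1  dwells move along the needle (arc-length shift)
#   2  prostate boundary expansion/contraction from its geometric centre,
#      with resampling back to the original slice width
#   3  urethra / rectum slice-wise contour expansion/contraction
#   4  per-needle transverse dwell displacement
#   5  dwell-time percentage scale and constant offset
#   6  rigid prostate motion (prostate, urethra and dwells move; rectum fixed)
# All operators are pure: the nominal case is never mutated.

#' One realisation of the six scenario parameters
#'
#' @param p1_shift dwell shift along the needle, mm; positive moves dwells
#'   towards the needle tip (superior).
#' @param p2_prostate prostate boundary expansion (+) / contraction (-), mm.
#' @param p3_urethra,p3_rectum slice-wise contour expansion/contraction, mm.
#' @param p4_transverse per-needle transverse movement, n_needles x 2 matrix
#'   of [X (left-right), Y (anterior-posterior)] in mm; or NULL for none.
#' @param p5_scale dwell-time multiplier (> 0); a p% change is `1 + p/100`.
#' @param p5_offset constant added to every dwell time, s.
#' @param p6_rigid rigid movement vector [X, Y, Z], mm.
#' @return object of class `scenario_params`.
#' @export
scenario_params <- function(p1_shift = 0, p2_prostate = 0, p3_urethra = 0,
                            p3_rectum = 0, p4_transverse = NULL,
                            p5_scale = 1, p5_offset = 0,
                            p6_rigid = c(0, 0, 0)) {
  stopifnot(p5_scale > 0, length(p6_rigid) == 3L)
  if (!is.null(p4_transverse)) {
    p4_transverse <- as.matrix(p4_transverse)
    stopifnot(ncol(p4_transverse) == 2L)
  }
  structure(list(p1_shift = p1_shift, p2_prostate = p2_prostate,
                 p3_urethra = p3_urethra, p3_rectum = p3_rectum,
                 p4_transverse = p4_transverse,
                 p5_scale = p5_scale, p5_offset = p5_offset,
                 p6_rigid = as.numeric(p6_rigid)),
            class = "scenario_params")
}

#' Parameter 1: move dwells along their needle
#'
#' Each dwell is mapped to its nearest path point, and relocated to the path
#' point whose arc length from the tip is nearest to the original arc length
#' minus `x` (positive `x` therefore moves dwells towards the tip, i.e.
#' superior).  Shifts beyond either path end clamp to the end point with a
#' warning.
#'
#' @param dwells a [dwell_set()].
#' @param paths `needle_paths` built from the nominal dwells.
#' @param x shift magnitude, mm.
#' @return updated [dwell_set()].
#' @export
shift_dwells_along_needle <- function(dwells, paths, x) {
  stopifnot(inherits(dwells, "dwell_set"), length(paths) == n_needles(dwells))
  n_clamped <- 0L
  positions <- dwells$positions
  for (i in seq_along(positions)) {
    P <- positions[[i]]
    pts <- paths[[i]]$points
    arcl <- paths[[i]]$arclengths
    amax <- arcl[length(arcl)]
    # nearest path index per dwell, vectorised over the dense path
    d2 <- outer(rowSums(P^2), rowSums(pts^2), "+") - 2 * P %*% t(pts)
    kmin <- max.col(-d2, ties.method = "first")
    for (j in seq_len(nrow(P))) {
      target <- arcl[kmin[j]] - x
      if (target < 0 || target > amax) n_clamped <- n_clamped + 1L
      target <- min(max(target, 0), amax)
      kx <- nearest_arclength_index(arcl, target)
      P[j, ] <- pts[kx, ]
    }
    positions[[i]] <- P
  }
  if (n_clamped > 0L)
    warning(sprintf("shift_dwells_along_needle: %d dwell(s) clamped at a path end",
                    n_clamped))
  dwell_set(positions, dwells$times, dwells$tips)
}

#' Parameter 2: prostate boundary expansion/contraction
#'
#' Every contour vertex moves by exactly `x` mm along the line joining it to
#' the whole-structure geometric centre (the mean of all vertices).  Because
#' this de-planarises the slices, the structure is then resampled back to
#' its original slice width: vertices with the same within-slice index form
#' superior-inferior boundary curves, each curve is refit with an
#' interpolating cubic spline against z, and re-evaluated on the uniform
#' z-grid of original slice width centred on the original mean z.
#'
#' Requires corresponding vertex counts across slices (true of template
#' phantom contours and of resampled clinical contours).
#'
#' @param structure prostate `structure_contours` (>= 3 slices).
#' @param x expansion (+) / contraction (-) magnitude, mm.
#' @return updated `structure_contours`.
#' @export
scale_prostate <- function(structure, x) {
  stopifnot(inherits(structure, "structure_contours"))
  ns <- length(structure$slices)
  if (ns < 3L) stop("scale_prostate: prostate needs >= 3 slices")
  nv <- vapply(structure$slices, nrow, integer(1))
  if (length(unique(nv)) != 1L)
    stop("scale_prostate: slices must have equal vertex counts for resampling")
  L <- nv[1]
  V <- all_vertices(structure)
  ctr <- colMeans(V)
  rel <- sweep(V, 2, ctr)
  dist <- sqrt(rowSums(rel^2))
  if (any(dist + x <= 0))
    stop("scale_prostate: contraction collapses a vertex through the centre")
  Vnew <- V + rel / dist * x

  # boundary curves: vertex l across slices, ordered inferior -> superior
  z0 <- structure_z(structure)
  zbar <- mean(z0)
  sw <- structure$slice_width
  curves <- lapply(seq_len(L), function(l) Vnew[seq(l, by = L, length.out = ns), , drop = FALSE])
  zmin <- max(vapply(curves, function(cv) min(cv[, 3]), numeric(1)))
  zmax <- min(vapply(curves, function(cv) max(cv[, 3]), numeric(1)))
  ks <- seq(ceiling((zmin - zbar) / sw - 1e-9), floor((zmax - zbar) / sw + 1e-9))
  zt <- zbar + ks * sw
  if (length(zt) < 3L)
    stop("scale_prostate: resampling left fewer than 3 slices")
  res <- array(NA_real_, dim = c(length(zt), L, 2))
  for (l in seq_len(L)) {
    cv <- curves[[l]]
    if (any(diff(cv[, 3]) <= 0))
      stop("scale_prostate: boundary curve z-coordinates are not monotone; cannot resample")
    res[, l, 1] <- stats::spline(cv[, 3], cv[, 1], xout = zt, method = "natural")$y
    res[, l, 2] <- stats::spline(cv[, 3], cv[, 2], xout = zt, method = "natural")$y
  }
  slices <- lapply(seq_along(zt), function(n)
    cbind(res[n, , 1], res[n, , 2], rep(zt[n], L)))
  structure_contours(slices, sw, name = structure$name)
}

#' Parameter 3: slice-wise contour expansion/contraction
#'
#' Per transverse slice, every vertex moves by exactly `x` mm along the line
#' joining it to that slice's centroid; z is unchanged and no resampling is
#' performed (these structures extend beyond their contoured extent).
#'
#' @param structure `structure_contours` (urethra or rectum).
#' @param x expansion (+) / contraction (-) magnitude, mm.
#' @return updated `structure_contours`.
#' @export
scale_structure_slicewise <- function(structure, x) {
  stopifnot(inherits(structure, "structure_contours"))
  slices <- structure$slices
  for (n in seq_along(slices)) {
    s <- slices[[n]]
    ctr <- colMeans(s[, 1:2, drop = FALSE])
    rel <- sweep(s[, 1:2, drop = FALSE], 2, ctr)
    dist <- sqrt(rowSums(rel^2))
    if (any(dist + x <= 0))
      stop(sprintf(
        "scale_structure_slicewise('%s'): contraction collapses slice %d (z = %.2f mm)",
        structure$name, n, s[1, 3]))
    s[, 1:2] <- s[, 1:2, drop = FALSE] + rel / dist * x
    slices[[n]] <- s
  }
  structure_contours(slices, structure$slice_width, name = structure$name)
}

#' Parameter 4: transverse needle displacement
#'
#' Translates every dwell of needle i by `[X_i, Y_i, 0]` (left-right,
#' anterior-posterior).  The source orientation along the needle path is not
#' updated.
#'
#' @param dwells a [dwell_set()].
#' @param vectors n_needles x 2 matrix of per-needle [X, Y] shifts, mm.
#' @return updated [dwell_set()].
#' @export
translate_needles_transverse <- function(dwells, vectors) {
  stopifnot(inherits(dwells, "dwell_set"))
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != n_needles(dwells) || ncol(vectors) != 2L)
    stop(sprintf("translate_needles_transverse: need one [X, Y] vector per needle (%d), got %d",
                 n_needles(dwells), nrow(vectors)))
  positions <- dwells$positions
  tips <- dwells$tips
  for (i in seq_along(positions)) {
    shift <- c(vectors[i, ], 0)
    positions[[i]] <- sweep(positions[[i]], 2, shift, "+")
    tips[[i]] <- tips[[i]] + shift
  }
  dwell_set(positions, dwells$times, tips)
}

#' Parameter 5: dwell-time scale and offset
#'
#' `t <- t * scale + offset` per dwell; negative results are clipped to zero
#' (dwell times are physically non-negative) with a warning reporting the
#' clip count.
#'
#' @param times list of per-needle dwell-time vectors (or a single numeric
#'   vector), seconds.
#' @param scale multiplier (> 0); a p% change is `1 + p/100`.
#' @param offset additive constant, s.
#' @return updated times of the same shape, with attribute `n_clipped`.
#' @export
adjust_dwell_times <- function(times, scale = 1, offset = 0) {
  stopifnot(scale > 0)
  plain <- !is.list(times)
  if (plain) times <- list(times)
  n_clipped <- 0L
  times <- lapply(times, function(tt) {
    tt <- tt * scale + offset
    n_clipped <<- n_clipped + sum(tt < 0)
    pmax(tt, 0)
  })
  if (n_clipped > 0L)
    warning(sprintf("adjust_dwell_times: %d dwell time(s) clipped at 0 s", n_clipped))
  out <- if (plain) times[[1]] else times
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Parameter 6: rigid prostate motion
#'
#' Simulates relative prostate-rectum rigid motion by translating the
#' prostate, urethra and all dwell points by the vector; the rectum stays
#' fixed.
#'
#' @param case a [case_model()].
#' @param vector length-3 [X, Y, Z] movement, mm.
#' @return updated [case_model()].
#' @export
rigid_move <- function(case, vector) {
  stopifnot(inherits(case, "case_model"), length(vector) == 3L)
  vector <- as.numeric(vector)
  move_str <- function(str) {
    slices <- lapply(str$slices, function(s) sweep(s, 2, vector, "+"))
    structure_contours(slices, str$slice_width, name = str$name)
  }
  dw <- case$dwells
  positions <- lapply(dw$positions, function(P) sweep(P, 2, vector, "+"))
  tips <- lapply(dw$tips, function(tp) tp + vector)
  case_model(dwell_set(positions, dw$times, tips),
             contour_set(move_str(case$contours$prostate),
                         move_str(case$contours$urethra),
                         case$contours$rectum),
             prescription = case$prescription,
             constraints = case$constraints)
}

#' Apply a full scenario to a nominal case
#'
#' Applies the six operators in fixed order 1 to 6.  Pure: the nominal case
#' is left untouched.
#'
#' @param case nominal [case_model()].
#' @param paths `needle_paths` built from the nominal dwells.
#' @param params a [scenario_params()].
#' @param urethra_diameter_mode if TRUE, the urethra magnitude is interpreted
#'   as a diameter change and halved before slice-wise scaling.
#' @return scenario [case_model()].
#' @export
apply_scenario <- function(case, paths, params,
                           urethra_diameter_mode = FALSE) {
  stopifnot(inherits(case, "case_model"), inherits(params, "scenario_params"))
  dwells <- case$dwells
  prostate <- case$contours$prostate
  urethra <- case$contours$urethra
  rectum <- case$contours$rectum

  if (params$p1_shift != 0)
    dwells <- shift_dwells_along_needle(dwells, paths, params$p1_shift)
  if (params$p2_prostate != 0)
    prostate <- scale_prostate(prostate, params$p2_prostate)
  if (params$p3_urethra != 0) {
    xu <- if (urethra_diameter_mode) params$p3_urethra / 2 else params$p3_urethra
    urethra <- scale_structure_slicewise(urethra, xu)
  }
  if (params$p3_rectum != 0)
    rectum <- scale_structure_slicewise(rectum, params$p3_rectum)
  if (!is.null(params$p4_transverse) && any(params$p4_transverse != 0))
    dwells <- translate_needles_transverse(dwells, params$p4_transverse)
  if (params$p5_scale != 1 || params$p5_offset != 0)
    dwells$times <- adjust_dwell_times(dwells$times, params$p5_scale,
                                       params$p5_offset)

  out <- case_model(dwells, contour_set(prostate, urethra, rectum),
                    prescription = case$prescription,
                    constraints = case$constraints)
  if (any(params$p6_rigid != 0))
    out <- rigid_move(out, params$p6_rigid)
  out
}
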