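#' @keywords internal
"_PACKAGE"

#' @useDynLib brachyrobust, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx spline rnorm qnorm pnorm sd quantile median t.test setNames
#' @importFrom utils write.csv read.csv head tail
NULL

# Shared coordinate convention: DICOM patient coordinate system, millimetres.
# x: patient-left positive, y: posterior positive, z: superior positive.
# Times in seconds, dose in Gy.

STRUCTURE_NAMES <- c("prostate", "urethra", "rectum")

#' Dwell set: per-needle dwell coordinates, times and tip control point
#'
#' @param positions list (one element per needle) of numeric matrices, one row
#'   per dwell, columns x/y/z in mm, ordered from the needle tip (superior)
#'   towards inferior.
#' @param times list of numeric vectors of dwell durations in seconds,
#'   parallel to `positions`.
#' @param tips list of length-3 numeric vectors, the needle-end (tip) control
#'   point of each needle, mm.
#' @return An object of class `dwell_set`.
#' @export
dwell_set <- function(positions, times, tips) {
  stopifnot(is.list(positions), is.list(times), is.list(tips))
  if (length(positions) == 0L) stop("dwell_set: a plan must contain at least one needle")
  if (length(positions) != length(times) || length(positions) != length(tips))
    stop("dwell_set: positions, times and tips must have one entry per needle")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 3L) stop("dwell_set: dwell positions must be n x 3 matrices")
    colnames(p) <- c("x", "y", "z")
    p
  })
  times <- lapply(times, as.numeric)
  for (i in seq_along(positions)) {
    if (nrow(positions[[i]]) < 1L)
      stop(sprintf("dwell_set: needle %d has zero dwells", i))
    if (nrow(positions[[i]]) != length(times[[i]]))
      stop(sprintf("dwell_set: needle %d has %d positions but %d times",
                   i, nrow(positions[[i]]), length(times[[i]])))
    if (any(times[[i]] < 0))
      stop(sprintf("dwell_set: needle %d has negative dwell times", i))
    if (length(tips[[i]]) != 3L)
      stop(sprintf("dwell_set: needle %d tip is not a 3-vector", i))
  }
  structure(list(positions = positions, times = times,
                 tips = lapply(tips, as.numeric)),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  nd <- vapply(x$positions, nrow, integer(1))
  cat(sprintf("<dwell_set> %d needles, %d dwells, total time %.2f s\n",
              length(x$positions), sum(nd), sum(unlist(x$times))))
  invisible(x)
}

#' Number of needles / dwells in a dwell set
#' @param dwells a [dwell_set()].
#' @return integer count.
#' @export
n_needles <- function(dwells) length(dwells$positions)

#' @rdname n_needles
#' @export
n_dwells <- function(dwells) sum(vapply(dwells$positions, nrow, integer(1)))

#' Contoured structure: stacked transverse polygon slices
#'
#' @param slices list of numeric matrices (n x 3, mm); each slice a closed
#'   simple polygon with constant z, ordered inferior to superior.
#' @param slice_width slice spacing in mm.
#' @param name structure name.
#' @param z_tol tolerance on slice-spacing uniformity, mm.
#' @return An object of class `structure_contours`.
#' @export
structure_contours <- function(slices, slice_width, name = "structure",
                               z_tol = 0.01) {
  stopifnot(is.list(slices), length(slices) >= 1L, slice_width > 0)
  slices <- lapply(slices, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("structure_contours: slices must be n x 3 matrices")
    if (nrow(s) < 3L) stop("structure_contours: each slice polygon needs >= 3 vertices")
    if (diff(range(s[, 3])) > 1e-9)
      stop("structure_contours: all z-coordinates within a slice must be equal")
    colnames(s) <- c("x", "y", "z")
    s
  })
  zs <- vapply(slices, function(s) s[1, 3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  if (length(zs) > 1L) {
    dz <- diff(zs)
    if (any(abs(dz - slice_width) > z_tol))
      stop(sprintf(
        "structure_contours('%s'): non-uniform slice spacing; spacings [%s] mm vs slice_width %.3f mm",
        name, paste(sprintf("%.3f", unique(round(dz, 3))), collapse = ", "),
        slice_width))
  }
  structure(list(slices = slices, slice_width = as.numeric(slice_width),
                 name = name),
            class = "structure_contours")
}

#' Slice z-coordinates of a contoured structure (inferior to superior)
#' @param str a `structure_contours`.
#' @return numeric vector, mm.
#' @export
structure_z <- function(str) vapply(str$slices, function(s) s[1, 3], numeric(1))

all_vertices <- function(str) do.call(rbind, str$slices)

#' Contour set holding the three named structures
#'
#' @param prostate,urethra,rectum `structure_contours` objects.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(prostate, urethra, rectum) {
  for (s in list(prostate, urethra, rectum))
    stopifnot(inherits(s, "structure_contours"))
  structure(list(prostate = prostate, urethra = urethra, rectum = rectum),
            class = "contour_set")
}

#' Clinical DVH constraints
#'
#' The default set quantifies the clinical objectives for a 16 Gy single
#' fraction: prostate D90 >= 16 Gy, V100 >= 90%, V150 <= 40%, V200 <= 10%;
#' urethra D10 <= 18.4 Gy, D0.01cc <= 18.4 Gy; rectum V75 <= 1.0 cc,
#' D0.1cc <= 13 Gy.  Boundary equality counts as a pass.
#'
#' @return data.frame with columns metric, structure, limit, direction, unit.
#' @export
default_constraints <- function() {
  data.frame(
    metric = c("D90", "V100", "V150", "V200", "D10", "D0.01cc", "V75", "D0.1cc"),
    structure = c(rep("prostate", 4), rep("urethra", 2), rep("rectum", 2)),
    limit = c(16, 90, 40, 10, 18.4, 18.4, 1.0, 13),
    direction = c(">=", ">=", "<=", "<=", "<=", "<=", "<=", "<="),
    unit = c("Gy", "%", "%", "%", "Gy", "Gy", "cc", "Gy"),
    stringsAsFactors = FALSE
  )
}

#' Canonical order of the eight clinical DVH metric names
#' @return character vector.
#' @export
metric_names <- function() default_constraints()$metric

#' Case model: the in-memory nominal treatment plan
#'
#' @param dwells a [dwell_set()].
#' @param contours a [contour_set()].
#' @param prescription prescription dose in Gy (single fraction).
#' @param constraints constraint table, see [default_constraints()].
#' @return An object of class `case_model`.
#' @export
case_model <- function(dwells, contours, prescription = 16,
                       constraints = default_constraints()) {
  stopifnot(inherits(dwells, "dwell_set"), inherits(contours, "contour_set"),
            prescription > 0)
  bad <- setdiff(constraints$structure, STRUCTURE_NAMES)
  if (length(bad))
    stop("case_model: constraints reference undefined structures: ",
         paste(bad, collapse = ", "))
  structure(list(dwells = dwells, contours = contours,
                 prescription = as.numeric(prescription),
                 constraints = constraints),
            class = "case_model")
}

#' @export
print.case_model <- function(x, ...) {
  cat(sprintf("<case_model> %d needles, %d dwells, prescription %.1f Gy\n",
              n_needles(x$dwells), n_dwells(x$dwells), x$prescription))
  for (nm in STRUCTURE_NAMES)
    cat(sprintf("  %-8s %d slices, slice width %.2f mm\n", nm,
                length(x$contours[[nm]]$slices), x$contours[[nm]]$slice_width))
  invisible(x)
}
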