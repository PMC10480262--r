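# Dose-volume histogram machinery: deterministic grid sampling of points
# inside stacked-contour structures, cumulative DVH curves, the eight
# clinical metrics (D90, V100, V150, V200, D10, D0.01cc, V75, D0.1cc) and
# constraint evaluation.

#' Sample dose-calculation points inside a contoured structure
#'
#' Lays a deterministic regular grid (spacing `spacing` mm in all three
#' axes, offset half a step from the structure's bounding box so no point
#' lies on the grid boundary) over the stacked-polygon volume.  A z-level is
#' evaluated against the polygon of its nearest slice provided it falls
#' inside that slice's extruded slab (slice z +/- slice_width/2).  Each
#' retained point carries a volume weight of `spacing^3` mm^3; the summed
#' weight estimates the structure volume.
#'
#' @param structure a `structure_contours`.
#' @param spacing grid spacing, mm (default 1).
#' @return list with `points` (n x 3 matrix, mm) and `weight` (mm^3 per
#'   point).
#' @export
sample_structure_points <- function(structure, spacing = 1) {
  stopifnot(inherits(structure, "structure_contours"), spacing > 0)
  zs <- structure_z(structure)
  sw <- structure$slice_width
  V <- all_vertices(structure)
  gx <- grid_axis(range(V[, 1]), spacing)
  gy <- grid_axis(range(V[, 2]), spacing)
  gz <- grid_axis(c(min(zs) - sw / 2, max(zs) + sw / 2), spacing)
  base <- as.matrix(expand.grid(x = gx, y = gy))
  out <- vector("list", length(gz))
  for (iz in seq_along(gz)) {
    isl <- which.min(abs(zs - gz[iz]))
    if (abs(zs[isl] - gz[iz]) > sw / 2) next
    poly <- structure$slices[[isl]][, 1:2, drop = FALSE]
    keep <- mgcv::in.out(rbind(poly, poly[1, ]), base)
    if (any(keep))
      out[[iz]] <- cbind(base[keep, , drop = FALSE], gz[iz])
  }
  pts <- do.call(rbind, out)
  if (is.null(pts) || nrow(pts) < 50L)
    stop(sprintf(
      "sample_structure_points('%s'): only %d points at spacing %.2f mm; use a finer spacing",
      structure$name, if (is.null(pts)) 0L else nrow(pts), spacing))
  colnames(pts) <- c("x", "y", "z")
  list(points = pts, weight = rep(spacing^3, nrow(pts)))
}

grid_axis <- function(rng, spacing) {
  n <- floor(diff(rng) / spacing)
  if (n < 1) return(mean(rng))
  mid <- mean(rng)
  mid + (seq_len(n) - (n + 1) / 2) * spacing
}

#' Cumulative DVH curve from weighted dose samples
#'
#' @param dose numeric vector of point doses, Gy.
#' @param weight per-point volume weights, mm^3.
#' @param bin_width dose bin width, Gy (default 0.01 for adequate binning).
#' @param max_dose top of the dose grid; defaults to the sample maximum.
#' @return object of class `dvh_curve`: `dose_bins` (Gy, uniform from 0),
#'   `rel_volume` (fraction receiving >= bin dose) and `abs_volume_cc`.
#' @export
compute_dvh <- function(dose, weight = rep(1, length(dose)), bin_width = 0.01,
                        max_dose = NULL) {
  stopifnot(length(dose) >= 1L, length(weight) == length(dose))
  if (is.null(max_dose)) max_dose <- max(dose)
  bins <- seq(0, max(max_dose, bin_width), by = bin_width)
  total <- sum(weight)
  # weighted survival function: fraction of volume with dose >= bin edge
  ord <- order(dose)
  cw <- cumsum(weight[ord])
  idx <- findInterval(bins - 1e-12, dose[ord])     # strictly-below count
  rel <- 1 - c(0, cw)[idx + 1L] / total
  structure(list(dose_bins = bins, rel_volume = rel,
                 abs_volume_cc = rel * total / 1000),
            class = "dvh_curve")
}

#' Minimum dose to the hottest volume fraction (D_x)
#'
#' Computed from weighted samples by descending-dose accumulation without
#' interpolation: the dose of the sample at which the accumulated hottest
#' volume first reaches the requested volume.
#'
#' @param dose point doses, Gy.
#' @param weight per-point volume weights, mm^3.
#' @param volume_pct hottest volume as a percentage of the structure volume
#'   (0 < x <= 100), or NULL if `volume_cc` is given.
#' @param volume_cc hottest volume in cc.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dose, weight = rep(1, length(dose)),
                           volume_pct = NULL, volume_cc = NULL) {
  stopifnot(length(dose) >= 1L)
  total <- sum(weight)
  if (is.null(volume_cc)) {
    stopifnot(!is.null(volume_pct), volume_pct > 0, volume_pct <= 100)
    target <- total * volume_pct / 100
  } else {
    target <- volume_cc * 1000
    if (target > total * (1 + 1e-9))
      stop(sprintf("dose_at_volume: requested %.3f cc exceeds structure volume %.3f cc",
                   volume_cc, total / 1000))
  }
  ord <- order(dose, decreasing = TRUE)
  cw <- cumsum(weight[ord])
  k <- which(cw >= target - 1e-9)[1]
  dose[ord[k]]
}

#' Volume receiving at least a dose level (V_y)
#'
#' @param dose point doses, Gy.
#' @param weight per-point volume weights, mm^3.
#' @param dose_level threshold, Gy.
#' @param as `"%"` for percentage of structure volume or `"cc"`.
#' @return volume in the requested unit.
#' @export
volume_at_dose <- function(dose, weight = rep(1, length(dose)), dose_level,
                           as = c("%", "cc")) {
  as <- match.arg(as)
  stopifnot(dose_level >= 0)
  v <- sum(weight[dose >= dose_level])
  if (as == "%") 100 * v / sum(weight) else v / 1000
}

#' Compute the eight clinical DVH metrics for a dosed case
#'
#' V100/V150/V200 (prostate) and V75 (rectum) are defined relative to the
#' prescription (100% = prescription dose).
#'
#' @param doses named list with elements `prostate`, `urethra`, `rectum`,
#'   each a list with `dose` (Gy) and `weight` (mm^3) for the structure's
#'   sample points.
#' @param prescription prescription dose, Gy.
#' @return named numeric vector of the eight metrics (D90, V100, V150, V200,
#'   D10, D0.01cc, V75, D0.1cc).
#' @export
compute_metrics <- function(doses, prescription = 16) {
  pr <- doses$prostate; ur <- doses$urethra; re <- doses$rectum
  c(D90 = dose_at_volume(pr$dose, pr$weight, volume_pct = 90),
    V100 = volume_at_dose(pr$dose, pr$weight, prescription, as = "%"),
    V150 = volume_at_dose(pr$dose, pr$weight, 1.5 * prescription, as = "%"),
    V200 = volume_at_dose(pr$dose, pr$weight, 2 * prescription, as = "%"),
    D10 = dose_at_volume(ur$dose, ur$weight, volume_pct = 10),
    "D0.01cc" = dose_at_volume(ur$dose, ur$weight, volume_cc = 0.01),
    V75 = volume_at_dose(re$dose, re$weight, 0.75 * prescription, as = "cc"),
    "D0.1cc" = dose_at_volume(re$dose, re$weight, volume_cc = 0.1))
}

#' Evaluate the clinical constraints on a metric set
#'
#' Boundary equality counts as a pass.
#'
#' @param metrics named numeric vector as from [compute_metrics()].
#' @param constraints constraint table, see [default_constraints()].
#' @return list with `pass` (named logical), `n_pass`, `n_total`,
#'   `all_pass`, and `all_pass_no_V200` (all constraints except V200).
#' @export
evaluate_constraints <- function(metrics, constraints = default_constraints()) {
  missing <- setdiff(constraints$metric, names(metrics))
  if (length(missing))
    stop("evaluate_constraints: missing metrics: ", paste(missing, collapse = ", "))
  pass <- vapply(seq_len(nrow(constraints)), function(i) {
    v <- metrics[[constraints$metric[i]]]
    if (constraints$direction[i] == ">=") v >= constraints$limit[i]
    else v <= constraints$limit[i]
  }, logical(1))
  names(pass) <- constraints$metric
  list(pass = pass, n_pass = sum(pass), n_total = length(pass),
       all_pass = all(pass),
       all_pass_no_V200 = all(pass[names(pass) != "V200"]))
}
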