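# TG-43 dose engine: dose rate around a cylindrically symmetric HDR source
# from the dose-rate constant, geometry function, radial dose function g(r)
# and 2D anisotropy function F(r, theta).  Dose to water in a homogeneous
# water medium; no shielding, scatter or transit-dose corrections.
#
# Evaluation strategy: at construction the source tables are combined into a
# fine uniform product grid T(r, cos theta) = g(r) G_ratio(r,theta)
# F(r,theta) r^2 (g interpolated log-linearly in r, F log-linearly in r and
# linearly in theta, G analytic), so a line-mode dose rate is one bilinear
# lookup: k T / r^2.  Beyond the grid the analytic slow path is used.  The
# pure-R dose_rate_at() and the C++ bulk kernel evaluate the identical grid
# with identical arithmetic, so they agree to floating-point precision.

FINE_DR <- 0.005  # cm; radial step of the g grid, hits r0 = 1 cm exactly
T_DR <- 0.02      # cm; radial step of the product grid
T_DCT <- 0.04     # cos(theta) step of the product grid; 0 is a knot

#' HDR source model for TG-43 dose calculation
#'
#' @param dose_rate_constant Lambda, cGy h^-1 U^-1.
#' @param air_kerma_strength S_K in U (1 U = 1 cGy cm^2 h^-1).
#' @param active_length active source length L, mm.
#' @param radial_dose data.frame with columns `r_cm`, `g`; must bracket
#'   r = 1 cm and is renormalised so g(1 cm) = 1.  Interpolated
#'   log-linearly in r; extrapolated log-linearly above the table maximum
#'   and held at the first value below the minimum.
#' @param anisotropy list with `r_cm` (vector), `theta_deg` (vector) and `F`
#'   (matrix r x theta); renormalised so F(r, 90 deg) = 1 row-wise;
#'   interpolated log-linearly in r, linearly in theta, clamped outside the
#'   grid.
#' @param mode `"line"` (line-source geometry function and 2D anisotropy) or
#'   `"point"` (inverse square, anisotropy = 1).
#' @return object of class `source_model`.
#' @export
source_model <- function(dose_rate_constant, air_kerma_strength, active_length,
                         radial_dose, anisotropy, mode = c("line", "point")) {
  mode <- match.arg(mode)
  stopifnot(dose_rate_constant > 0, air_kerma_strength > 0, active_length > 0)
  r <- as.numeric(radial_dose$r_cm); g <- as.numeric(radial_dose$g)
  if (any(diff(r) <= 0)) stop("source_model: radial dose table r must be strictly increasing")
  if (min(r) > 1 || max(r) < 1) stop("source_model: radial dose table must bracket r0 = 1 cm")
  g <- g / stats::approx(log(r), g, xout = 0)$y   # enforce g(1 cm) = 1
  rf <- as.numeric(anisotropy$r_cm); th <- as.numeric(anisotropy$theta_deg)
  Fm <- as.matrix(anisotropy$F)
  if (any(diff(rf) <= 0)) stop("source_model: anisotropy table r must be strictly increasing")
  stopifnot(nrow(Fm) == length(rf), ncol(Fm) == length(th))
  f90 <- vapply(seq_along(rf), function(i) stats::approx(th, Fm[i, ], xout = 90)$y,
                numeric(1))
  Fm <- Fm / f90
  nr <- length(r)

  src <- list(dose_rate_constant = dose_rate_constant,
              air_kerma_strength = air_kerma_strength,
              active_length = active_length,
              radial_dose = data.frame(r_cm = r, g = g),
              anisotropy = list(r_cm = rf, theta_deg = th, F = Fm),
              mode = mode)

  # fine uniform radial grid for g (point mode and the slow path)
  n_g <- floor((max(r) - min(r)) / FINE_DR + 1e-9) + 1L
  src$g_fine_r0 <- min(r)
  src$g_fine_rmax <- src$g_fine_r0 + FINE_DR * (n_g - 1)
  src$g_fine <- stats::approx(log(r), g,
                              xout = log(src$g_fine_r0 + FINE_DR * (seq_len(n_g) - 1)))$y
  src$g_hi_slope <- (g[nr] - g[nr - 1]) / (log(r[nr]) - log(r[nr - 1]))
  src$g_logr_max <- log(r[nr])
  src$g_max_val <- g[nr]

  # product grid T(r, ct) = g G_ratio F r^2 for the line-mode fast path
  n_tr <- floor((max(r) - min(r)) / T_DR + 1e-9) + 1L
  src$T_r0 <- min(r)
  src$T_rmax <- src$T_r0 + T_DR * (n_tr - 1)
  rT <- src$T_r0 + T_DR * (seq_len(n_tr) - 1)
  ct_knots <- seq(-1, 1, by = T_DCT)
  th_knots <- acos(pmin(pmax(ct_knots, -1), 1)) * 180 / pi
  gT <- stats::approx(log(r), g, xout = log(rT))$y
  # F at (rT, th_knots): theta interpolation per original radius row, then log-r
  Fth <- t(vapply(seq_along(rf), function(i)
    stats::approx(th, Fm[i, ], xout = th_knots, rule = 2)$y,
    numeric(length(th_knots))))
  FT <- vapply(seq_along(ct_knots), function(j)
    stats::approx(log(rf), Fth[, j], xout = log(rT), rule = 2)$y,
    numeric(n_tr))
  L_cm <- active_length / 10
  GT <- vapply(seq_along(ct_knots), function(j) {
    ct <- ct_knots[j]
    geometry_ratio(rT, sqrt(max(1 - ct * ct, 0)), ct, L_cm)
  }, numeric(n_tr))
  src$T_fine <- gT * GT * FT * rT^2
  class(src) <- "source_model"
  src
}

#' Bundled generic Ir-192 source model
#'
#' A generic high-dose-rate Ir-192 stepping source with smooth synthetic
#' radial-dose and anisotropy tables of realistic shape (not a consensus
#' dataset for any commercial source; substitute clinic-measured tables via
#' [source_model()] for clinical use).  Default air-kerma strength 40700 U
#' (approximately a fresh 10 Ci source), dose-rate constant 1.109
#' cGy h^-1 U^-1, active length 3.5 mm.
#'
#' @param air_kerma_strength S_K in U.
#' @param mode `"line"` or `"point"`.
#' @return a `source_model`.
#' @export
default_source <- function(air_kerma_strength = 40700, mode = "line") {
  gd <- read.delim(system.file("extdata", "ir192_generic_radial_dose.tsv",
                               package = "brachyrobust"))
  an <- read.delim(system.file("extdata", "ir192_generic_anisotropy.tsv",
                               package = "brachyrobust"), check.names = FALSE)
  source_model(dose_rate_constant = 1.109,
               air_kerma_strength = air_kerma_strength,
               active_length = 3.5,
               radial_dose = data.frame(r_cm = gd$r_cm, g = gd$g),
               anisotropy = list(r_cm = an[[1]],
                                 theta_deg = as.numeric(colnames(an)[-1]),
                                 F = as.matrix(an[, -1])),
               mode = mode)
}

#' Normalised line-source geometry function ratio
#'
#' `G_L(r, theta) / G_L(1 cm, 90 deg)` with `G_L = beta / (L r sin theta)`
#' where beta is the angle subtended by the active length at the calculation
#' point.  On the source axis the limit `1 / (r^2 - L^2/4)` is used.  As
#' L -> 0 the ratio tends to the inverse-square `1 / r^2`.
#'
#' @param r distance source centre to point, cm (> 0).
#' @param theta polar angle from the source axis, degrees.
#' @param L active length, cm.
#' @return unitless ratio (vectorised over `r` and `theta`).
#' @export
line_geometry_factor <- function(r, theta, L) {
  if (any(r <= 0)) stop("line_geometry_factor: r must be > 0 (source-centre singularity)")
  stopifnot(L > 0)
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  th <- theta * pi / 180
  st <- sin(th); ct <- cos(th)
  geometry_ratio(r, st, ct, L)
}

# core geometry ratio from sin/cos of the polar angle; mirrored in C++.
# The line geometry function diverges on the active-length segment itself
# (polar angles near 0/180 deg at radii comparable to L/2, a region where
# the TG-43 data are not valid); it is regularised there by capping at the
# value obtained with sin(theta) floored at 0.1.
geometry_ratio <- function(r, st, ct, L) {
  n <- max(length(r), length(st))
  r <- rep_len(r, n); st <- rep_len(st, n)
  h <- L / 2
  # beta = atan2(2 h r sin(theta), r^2 - h^2) covers both quadrants
  beta <- atan2(2 * h * r * st, r * r - h * h)
  gref <- atan2(2 * h, 1 - h * h) / L
  G <- ifelse(abs(st) > 1e-7,
              beta / (L * r * st),
              1 / pmax(r * r - h * h, 1e-9))
  pmin(G, pi / (L * r * 0.1)) / gref
}

# fine-grid interpolators; the C++ kernel repeats this arithmetic verbatim
interp_g_fine <- function(source, r_cm) {
  if (r_cm >= source$g_fine_rmax) {
    g <- source$g_max_val + source$g_hi_slope * (log(r_cm) - source$g_logr_max)
    return(list(g = g, above = r_cm > source$g_fine_rmax + 1e-12))
  }
  u <- (r_cm - source$g_fine_r0) / FINE_DR
  if (u <= 0) return(list(g = source$g_fine[1]))
  i <- floor(u); w <- u - i
  list(g = source$g_fine[i + 1] * (1 - w) + source$g_fine[i + 2] * w)
}

interp_T_fine <- function(source, r_cm, ct) {
  u <- (r_cm - source$T_r0) / T_DR
  i <- max(min(floor(u), nrow(source$T_fine) - 2), 0)
  wu <- u - i
  v <- (min(max(ct, -1), 1) + 1) / T_DCT
  j <- min(floor(v), ncol(source$T_fine) - 2)
  wv <- v - j
  Tm <- source$T_fine
  (1 - wu) * ((1 - wv) * Tm[i + 1, j + 1] + wv * Tm[i + 1, j + 2]) +
    wu * ((1 - wv) * Tm[i + 2, j + 1] + wv * Tm[i + 2, j + 2])
}

# slow-path anisotropy from the original tables: log-linear in r (clamped),
# linear in theta (clamped)
interp_F_orig <- function(source, r_cm, theta) {
  rf <- source$anisotropy$r_cm; th <- source$anisotropy$theta_deg
  Fm <- source$anisotropy$F
  lr <- min(max(log(r_cm), log(rf[1])), log(rf[length(rf)]))
  thc <- min(max(theta, th[1]), th[length(th)])
  row <- vapply(seq_along(th), function(j)
    stats::approx(log(rf), Fm[, j], xout = lr)$y, numeric(1))
  stats::approx(th, row, xout = thc)$y
}

#' TG-43 dose rate at a point from a single dwell
#'
#' `S_K Lambda G(r,theta)/G(r0,theta0) g(r) F(r,theta)` converted to Gy/s.
#' Point mode drops the anisotropy (F = 1) and uses inverse-square geometry.
#' Distances below the radial table minimum are evaluated at the minimum
#' (nearest-value cap, transverse angle) with a warning; above the maximum,
#' g is extrapolated log-linearly with a warning.
#'
#' @param source a `source_model`.
#' @param dwell_pos source centre, mm.
#' @param dwell_dir unit vector along the source axis.
#' @param point calculation point, mm.
#' @return dose rate in Gy/s.
#' @export
dose_rate_at <- function(source, dwell_pos, dwell_dir, point) {
  d <- as.numeric(point) - as.numeric(dwell_pos)
  r_mm <- sqrt(sum(d^2))
  if (r_mm == 0) stop("dose_rate_at: point coincides with the dwell position")
  r_cm <- r_mm / 10
  capped <- r_cm < source$g_fine_r0
  r_eval <- max(r_cm, source$g_fine_r0)
  if (capped)
    warning(sprintf("dose_rate_at: r = %.4f cm below table minimum; capped at %.2f cm",
                    r_cm, source$g_fine_r0))
  k <- source$air_kerma_strength * source$dose_rate_constant / 3.6e5  # cGy/h -> Gy/s
  if (source$mode == "point") {
    gi <- interp_g_fine(source, r_eval)
    if (isTRUE(gi$above))
      warning("dose_rate_at: r above radial table maximum; g extrapolated log-linearly")
    return(k * gi$g / (r_eval * r_eval))
  }
  ct <- if (capped) 0 else {
    v <- sum(d * dwell_dir) / r_mm
    min(max(v, -1), 1)
  }
  if (r_eval >= source$T_rmax) {
    warning("dose_rate_at: r above radial table maximum; g extrapolated log-linearly")
    gi <- interp_g_fine(source, r_eval)
    st <- sqrt(max(1 - ct * ct, 0))
    G <- geometry_ratio(r_eval, st, ct, source$active_length / 10)
    return(k * G * gi$g * interp_F_orig(source, r_eval, acos(ct) * 180 / pi))
  }
  k * interp_T_fine(source, r_eval, ct) / (r_eval * r_eval)
}

#' Accumulate TG-43 dose from all dwells at a set of points
#'
#' Sums `rate(dwell, point) * t_dwell` over every dwell of every needle;
#' exactly linear in each dwell time.  The source axis at a dwell is the
#' local tangent of its needle path.  Points closer to a dwell than the
#' radial-table minimum have that contribution capped at the minimum-r value
#' (warning logged with a count).
#'
#' @param case a [case_model()] (scenario or nominal).
#' @param paths `needle_paths` for the case's needles (for source
#'   orientations); if NULL, straight superior-inferior orientation is used.
#' @param source a `source_model`.
#' @param points n x 3 matrix of calculation points, mm.
#' @param weights optional per-point volume weights, mm^3.
#' @param dirs optional precomputed n_dwells x 3 matrix of source-axis unit
#'   vectors (see [dwell_directions()]); by default derived from `paths`.
#' @return object of class `dose_sample`: list with `points`, `dose` (Gy),
#'   `weight`, and warning counts `n_below_min`, `n_above_max`.
#' @export
accumulate_dose <- function(case, paths, source, points, weights = NULL,
                            dirs = NULL) {
  stopifnot(inherits(case, "case_model"), inherits(source, "source_model"))
  points <- as.matrix(points)
  dw <- case$dwells
  pos <- do.call(rbind, dw$positions)
  times <- unlist(dw$times)
  if (is.null(dirs)) dirs <- dwell_directions(dw, paths)
  k <- source$air_kerma_strength * source$dose_rate_constant / 3.6e5
  res <- cpp_accumulate_dose(points, pos, dirs, times,
                             source$active_length / 10, k,
                             source$g_fine_r0, FINE_DR, source$g_fine,
                             source$g_hi_slope, source$g_logr_max,
                             source$g_max_val,
                             source$T_r0, source$T_fine,
                             source$anisotropy$r_cm, source$anisotropy$theta_deg,
                             source$anisotropy$F,
                             source$mode == "line")
  if (res$n_below_min > 0)
    warning(sprintf("accumulate_dose: %d dwell-point pairs below the radial table minimum (capped)",
                    res$n_below_min))
  structure(list(points = points, dose = res$dose,
                 weight = if (is.null(weights)) rep(1, nrow(points)) else weights,
                 n_below_min = res$n_below_min, n_above_max = res$n_above_max),
            class = "dose_sample")
}

#' Source-axis orientation of every dwell
#'
#' Local tangent of the needle path at the path point nearest each dwell
#' (straight superior orientation when `paths` is NULL).  The orientation is
#' assumed unchanged when dwells are displaced transversally, so directions
#' computed on the nominal plan are reused across scenarios.
#'
#' @param dwells a [dwell_set()].
#' @param paths `needle_paths` or NULL.
#' @return n_dwells x 3 matrix of unit vectors.
#' @export
dwell_directions <- function(dwells, paths) {
  nd <- n_dwells(dwells)
  dirs <- matrix(rep(c(0, 0, 1), each = nd), nd, 3)
  if (is.null(paths)) return(dirs)
  row <- 0L
  for (i in seq_len(n_needles(dwells))) {
    P <- dwells$positions[[i]]
    for (j in seq_len(nrow(P))) {
      row <- row + 1L
      dirs[row, ] <- path_tangent(paths[[i]],
                                  nearest_path_index(paths[[i]], P[j, ]))
    }
  }
  dirs
}
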