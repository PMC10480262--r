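# Shared fixtures, built in code and cached for the test session.

.fixture_env <- new.env(parent = emptyenv())

# the full default phantom (normalised at 1 mm grid), built once
cached_phantom <- function() {
  if (is.null(.fixture_env$phantom))
    .fixture_env$phantom <- suppressWarnings(phantom_case())
  .fixture_env$phantom
}

cached_paths <- function() {
  if (is.null(.fixture_env$paths))
    .fixture_env$paths <- build_needle_paths(cached_phantom()$dwells)
  .fixture_env$paths
}

cached_source <- function() {
  if (is.null(.fixture_env$source))
    .fixture_env$source <- default_source()
  .fixture_env$source
}

cached_dirs <- function() {
  if (is.null(.fixture_env$dirs))
    .fixture_env$dirs <- dwell_directions(cached_phantom()$dwells, cached_paths())
  .fixture_env$dirs
}

# a source with flat g and isotropic F: isolates the geometry function
flat_source <- function(active_length = 3.5, mode = "line",
                        air_kerma_strength = 40700) {
  r <- c(0.1, 0.5, 1, 2, 5, 10)
  source_model(dose_rate_constant = 1.109,
               air_kerma_strength = air_kerma_strength,
               active_length = active_length,
               radial_dose = data.frame(r_cm = r, g = rep(1, length(r))),
               anisotropy = list(r_cm = c(0.25, 1, 5, 10),
                                 theta_deg = c(0, 90, 180),
                                 F = matrix(1, 4, 3)),
               mode = mode)
}

# circular-tube structure along z
tube_structure <- function(radius, z_vals, centre = c(0, 0), nv = 24,
                           name = "structure") {
  sw <- if (length(z_vals) > 1) diff(z_vals)[1] else 1
  slices <- lapply(z_vals, function(z) {
    ang <- 2 * pi * (seq_len(nv) - 1) / nv
    cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang), z)
  })
  structure_contours(slices, sw, name = name)
}

# sphere approximated by stacked circular slices
sphere_structure <- function(radius, slice_width = 1, nv = 64,
                             name = "sphere") {
  nz <- floor((radius - slice_width / 4) / slice_width)
  zs <- seq(-nz, nz) * slice_width
  slices <- lapply(zs, function(z) {
    r <- sqrt(max(radius^2 - z^2, 1e-6))
    ang <- 2 * pi * (seq_len(nv) - 1) / nv
    cbind(r * cos(ang), r * sin(ang), z)
  })
  structure_contours(slices, slice_width, name = name)
}

# minimal single-needle case with simple tube structures
tiny_case <- function(n_dwells = 3, dwell_spacing = 5, time = 10) {
  zt <- seq(0, by = -dwell_spacing, length.out = n_dwells)
  dw <- dwell_set(list(cbind(0, 0, zt)), list(rep(time, n_dwells)),
                  list(c(0, 0, 2)))
  pro <- tube_structure(15, seq(-15, 5, by = 2.5), name = "prostate")
  ure <- tube_structure(3, seq(-20, 10, by = 2.5), name = "urethra")
  rec <- tube_structure(8, seq(-25, 10, by = 2.5), centre = c(0, 25),
                        name = "rectum")
  case_model(dw, contour_set(pro, ure, rec))
}

# deep copy via serialisation (for purity checks)
deep_copy <- function(x) unserialize(serialize(x, NULL))
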