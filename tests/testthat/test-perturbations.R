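test_that("dwell shift along needle: identity, arithmetic and sign", {
  dw <- dwell_set(list(cbind(0, 0, c(-5, -10, -15))), list(rep(1, 3)),
                  list(c(0, 0, 0)))
  paths <- build_needle_paths(dw, 6000)

  # zero shift reproduces positions within the interpolation resolution
  s0 <- shift_dwells_along_needle(dw, paths, 0)
  expect_lt(max(abs(s0$positions[[1]] - dw$positions[[1]])), 0.01)

  # straight needle along z: dwell 5 mm from tip, +2 mm -> 3 mm from tip
  s2 <- shift_dwells_along_needle(dw, paths, 2)
  expect_equal(unname(s2$positions[[1]][1, 3]), -3, tolerance = 1e-2)
  # positive shift moves every dwell superior (towards the tip)
  expect_true(all(s2$positions[[1]][, 3] > dw$positions[[1]][, 3]))

  # inferior shift beyond the path end clamps with a warning
  expect_warning(s3 <- shift_dwells_along_needle(dw, paths, -4), "clamped")
  expect_equal(unname(s3$positions[[1]][3, 3]), -15, tolerance = 1e-2)
})

test_that("phantom-wide shift decreases every arc-length coordinate by x", {
  case <- cached_phantom()
  paths <- cached_paths()
  x <- 2.47
  shifted <- suppressWarnings(shift_dwells_along_needle(case$dwells, paths, x))
  for (i in seq_len(n_needles(case$dwells))) {
    arcl <- paths[[i]]$arclengths
    for (j in seq_len(nrow(case$dwells$positions[[i]]))) {
      a0 <- arcl[nearest_path_index(paths[[i]], case$dwells$positions[[i]][j, ])]
      a1 <- arcl[nearest_path_index(paths[[i]], shifted$positions[[i]][j, ])]
      if (a0 - x >= 0)  # unclamped dwells only
        expect_equal(a1, a0 - x, tolerance = 0.02 / max(a0 - x, 1))
    }
  }
})

test_that("prostate scaling moves vertices radially and resamples slices", {
  sph <- sphere_structure(20, slice_width = 2, nv = 48)

  # identity within resampling tolerance
  s0 <- scale_prostate(sph, 0)
  expect_equal(length(s0$slices), length(sph$slices))
  for (n in seq_along(s0$slices))
    expect_lt(max(abs(s0$slices[[n]] - sph$slices[[n]])), 0.05)

  # sphere +2 mm: all resampled vertices at radius 22 +/- 0.1
  s2 <- scale_prostate(sph, 2)
  V <- do.call(rbind, s2$slices)
  ctr <- colMeans(do.call(rbind, sph$slices))
  rr <- sqrt(rowSums(sweep(V, 2, ctr)^2))
  expect_true(all(abs(rr - 22) < 0.1))
  # slice spacing preserved and centred on the original mean z
  zs <- vapply(s2$slices, function(s) s[1, 3], numeric(1))
  expect_equal(unique(round(diff(zs), 9)), 2)
  expect_true(any(abs(zs - mean(vapply(sph$slices, function(s) s[1, 3],
                                       numeric(1)))) < 1e-6))

  # volume strictly increases under expansion on the phantom prostate
  pro <- cached_phantom()$contours$prostate
  v0 <- sum(sample_structure_points(pro, 1)$weight)
  v1 <- sum(sample_structure_points(scale_prostate(pro, 1.65), 1)$weight)
  expect_gt(v1, v0)

  expect_error(scale_prostate(sph, -25), "collapses")
  expect_error(scale_prostate(tube_structure(5, c(0, 1)), 1), ">= 3 slices")
})

test_that("slice-wise scaling is exact on circles and reversible", {
  tube <- tube_structure(2.5, seq(0, 10, by = 2.5), nv = 16)
  s <- scale_structure_slicewise(tube, 0.5)
  for (sl in s$slices) {
    rr <- sqrt(rowSums(sweep(sl[, 1:2], 2, colMeans(sl[, 1:2]))^2))
    expect_equal(rr, rep(3.0, 16), tolerance = 1e-12)
    expect_equal(unique(unname(sl[, 3])), unname(sl[1, 3]))  # z unchanged
  }
  expect_equal(scale_structure_slicewise(tube, 0)$slices, tube$slices)

  # ellipse slice: every vertex moves exactly |x| along its centroid ray
  ang <- 2 * pi * (0:15) / 16
  ell <- structure_contours(list(cbind(6 * cos(ang), 3 * sin(ang), 0)), 1)
  e <- scale_structure_slicewise(ell, -0.3)
  d0 <- sqrt(rowSums(ell$slices[[1]][, 1:2]^2))
  d1 <- sqrt(rowSums(e$slices[[1]][, 1:2]^2))
  expect_equal(d0 - d1, rep(0.3, 16), tolerance = 1e-12)

  # +x then -x returns the original vertices
  back <- scale_structure_slicewise(scale_structure_slicewise(tube, 0.7), -0.7)
  expect_equal(unlist(back$slices), unlist(tube$slices), tolerance = 1e-9)

  err <- expect_error(scale_structure_slicewise(tube, -3), "collapses slice")
  expect_match(conditionMessage(err), "slice 1")
})

test_that("transverse needle translation shifts x/y only and checks counts", {
  case <- tiny_case(n_dwells = 3)
  t0 <- translate_needles_transverse(case$dwells, matrix(c(1, -2), 1, 2))
  expect_equal(t0$positions[[1]][, 1] - case$dwells$positions[[1]][, 1],
               rep(1, 3))
  expect_equal(t0$positions[[1]][, 2] - case$dwells$positions[[1]][, 2],
               rep(-2, 3))
  expect_equal(t0$positions[[1]][, 3], case$dwells$positions[[1]][, 3])

  tz <- translate_needles_transverse(case$dwells, matrix(0, 1, 2))
  expect_equal(tz$positions, case$dwells$positions)
  expect_error(translate_needles_transverse(case$dwells, matrix(0, 2, 2)),
               "per needle")

  # pairwise distances within the translated set are preserved
  ph <- cached_phantom()
  vecs <- matrix(rep(c(0, 0.82), each = 16), 16, 2)
  tp <- translate_needles_transverse(ph$dwells, vecs)
  P0 <- do.call(rbind, ph$dwells$positions)
  P1 <- do.call(rbind, tp$positions)
  idx <- seq(1, nrow(P0), by = 7)
  expect_equal(as.numeric(dist(P0[idx, ])), as.numeric(dist(P1[idx, ])),
               tolerance = 1e-12)
})

test_that("dwell time adjustment scales, offsets and clips at zero", {
  expect_equal(adjust_dwell_times(c(1, 2, 3), 1, 0), c(1, 2, 3),
               ignore_attr = TRUE)
  expect_equal(adjust_dwell_times(10, 1.072, 0), 10.72, ignore_attr = TRUE)
  expect_warning(out <- adjust_dwell_times(c(0.03, 5), 1, -0.06), "clipped")
  expect_equal(as.numeric(out), c(0, 4.94))
  expect_equal(attr(out, "n_clipped"), 1L)
  lst <- adjust_dwell_times(list(c(1, 2), 3), 2, 0.5)
  expect_equal(lst[[1]], c(2.5, 4.5))
  expect_equal(lst[[2]], 6.5)
})

test_that("rigid move translates prostate, urethra and dwells but not rectum", {
  case <- cached_phantom()
  v <- c(0.1, 0.5, 0)
  moved <- rigid_move(case, v)
  cen <- function(str) colMeans(do.call(rbind, str$slices))
  expect_equal(cen(moved$contours$prostate) - cen(case$contours$prostate), v,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cen(moved$contours$urethra) - cen(case$contours$urethra), v,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cen(moved$contours$rectum), cen(case$contours$rectum),
               tolerance = 1e-12)
  P0 <- do.call(rbind, case$dwells$positions)
  P1 <- do.call(rbind, moved$dwells$positions)
  expect_equal(colMeans(P1) - colMeans(P0), v, tolerance = 1e-12,
               ignore_attr = TRUE)

  # prostate-dwell relative geometry is preserved under any vector
  V0 <- rbind(P0[seq(1, nrow(P0), by = 11), ],
              case$contours$prostate$slices[[3]][1:5, ])
  m2 <- rigid_move(case, c(-1.3, 2.2, 0.4))
  V1 <- rbind(do.call(rbind, m2$dwells$positions)[seq(1, nrow(P0), by = 11), ],
              m2$contours$prostate$slices[[3]][1:5, ])
  expect_equal(as.numeric(dist(V0)), as.numeric(dist(V1)), tolerance = 1e-9)

  expect_equal(rigid_move(case, c(0, 0, 0))$dwells$positions,
               case$dwells$positions)
})

test_that("apply_scenario is pure and respects operator semantics", {
  case <- cached_phantom()
  paths <- cached_paths()
  snapshot <- deep_copy(case)

  set.seed(5)
  params <- scenario_params(p1_shift = 1.2, p2_prostate = -0.8,
                            p3_urethra = 0.3, p3_rectum = -0.5,
                            p4_transverse = matrix(rnorm(32, 0, 1), 16, 2),
                            p5_scale = 1.05, p5_offset = 0.02,
                            p6_rigid = c(0.1, -0.4, 0))
  scen <- suppressWarnings(apply_scenario(case, paths, params))
  expect_identical(case, snapshot)  # input untouched
  expect_s3_class(scen, "case_model")
  expect_false(identical(scen$dwells$positions, case$dwells$positions))

  # all-zero params leave the model identical (operators short-circuit)
  expect_identical(apply_scenario(case, paths, scenario_params())$dwells,
                   case$dwells)

  # urethra diameter mode halves the applied radial change
  p3 <- scenario_params(p3_urethra = 1)
  full <- apply_scenario(case, paths, p3)
  half <- apply_scenario(case, paths, p3, urethra_diameter_mode = TRUE)
  r_of <- function(cs) {
    sl <- cs$contours$urethra$slices[[1]]
    mean(sqrt(rowSums(sweep(sl[, 1:2], 2, colMeans(sl[, 1:2]))^2)))
  }
  expect_equal(r_of(full) - r_of(case), 1, tolerance = 1e-9)
  expect_equal(r_of(half) - r_of(case), 0.5, tolerance = 1e-9)
})

test_that("pure time scaling multiplies every dose metric exactly", {
  case <- cached_phantom()
  paths <- cached_paths()
  src <- cached_source()
  base <- suppressWarnings(run_scenario(case, paths, src, scenario_params(),
                                        spacing = 2, curve_max = NULL))
  up <- suppressWarnings(run_scenario(case, paths, src,
                                      scenario_params(p5_scale = 1.1),
                                      spacing = 2, curve_max = NULL))
  dm <- c("D90", "D10", "D0.01cc", "D0.1cc")
  expect_equal(up$metrics[dm], 1.1 * base$metrics[dm], tolerance = 1e-12)
  # V-metrics at a level scaled with the dose are unchanged
  sp <- sample_structure_points(case$contours$prostate, 2)
  dirs <- cached_dirs()
  d0 <- suppressWarnings(accumulate_dose(case, paths, src, sp$points,
                                         sp$weight, dirs))
  expect_equal(volume_at_dose(1.1 * d0$dose, d0$weight, 1.1 * 16),
               volume_at_dose(d0$dose, d0$weight, 16), tolerance = 1e-12)
})
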