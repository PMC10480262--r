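test_that("line geometry factor: normalisation, limits and quadrature oracle", {
  expect_equal(line_geometry_factor(1, 90, 0.35), 1, tolerance = 1e-12)
  # inverse-square limit as L -> 0
  expect_equal(line_geometry_factor(2, 90, 1e-6), 0.25, tolerance = 1e-6)
  expect_equal(line_geometry_factor(2, 37, 1e-6), 0.25, tolerance = 1e-6)
  expect_error(line_geometry_factor(0, 90, 0.35), "r must be > 0")

  # numerical quadrature oracle for the line-segment kernel
  gl_quad <- function(r, theta_deg, L) {
    th <- theta_deg * pi / 180
    p <- c(r * sin(th), r * cos(th))
    f <- function(l) 1 / ((p[1])^2 + (p[2] - l)^2)
    G <- integrate(f, -L / 2, L / 2, rel.tol = 1e-12)$value / L
    Gref <- integrate(function(l) 1 / (1 + l^2), -L / 2, L / 2,
                      rel.tol = 1e-12)$value / L
    G / Gref
  }
  for (cs in list(c(0.5, 30), c(1, 90), c(0.7, 120), c(2, 45), c(0.3, 80))) {
    expect_equal(line_geometry_factor(cs[1], cs[2], 0.35),
                 gl_quad(cs[1], cs[2], 0.35), tolerance = 1e-6)
  }
})

test_that("dose rate: point-mode reference conditions", {
  src <- default_source(mode = "point")
  k <- 40700 * 1.109 / 3.6e5
  # at (r0 = 1 cm, transverse): rate = S_K * Lambda, converted to Gy/s
  expect_equal(dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(10, 0, 0)), k,
               tolerance = 1e-9)
  # doubling r divides the rate by four (up to g(r) variation)
  g <- src$radial_dose
  g1 <- approx(log(g$r_cm), g$g, xout = log(1))$y
  g2 <- approx(log(g$r_cm), g$g, xout = log(2))$y
  r1 <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(10, 0, 0))
  r2 <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(20, 0, 0))
  expect_equal(r2 / r1, (g2 / g1) / 4, tolerance = 1e-3)
  expect_error(dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(0, 0, 0)),
               "coincides")
})

test_that("line mode matches a discretised multi-point-source oracle", {
  src <- flat_source(active_length = 3.5)  # g = 1, F = 1: geometry only
  k <- 40700 * 1.109 / 3.6e5
  nseg <- 4001
  lpos <- seq(-3.5 / 2, 3.5 / 2, length.out = nseg)  # mm along the axis
  set.seed(3)
  for (q in 1:12) {
    r <- runif(1, 0.5, 4); th <- runif(1, 5, 175)
    pt <- 10 * c(r * sin(th * pi / 180), 0, r * cos(th * pi / 180))
    got <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), pt)
    d2 <- (pt[1])^2 + (pt[3] - lpos)^2             # mm^2
    ref <- mean(100 / (100 + lpos^2))              # same sum at (1 cm, 90 deg)
    want <- k * mean(100 / d2) / ref               # normalised segment sum
    expect_equal(got, want, tolerance = 5e-3)
  }
})

test_that("line mode converges to point mode as L -> 0", {
  srcL <- flat_source(active_length = 1e-3)  # 1e-4 cm
  srcP <- flat_source(mode = "point")
  set.seed(4)
  for (q in 1:10) {
    pt <- c(runif(1, -30, 30), runif(1, -30, 30), runif(1, -30, 30))
    if (sqrt(sum(pt^2)) < 2) pt <- pt + 5
    rl <- dose_rate_at(srcL, c(0, 0, 0), c(0, 0, 1), pt)
    rp <- dose_rate_at(srcP, c(0, 0, 0), c(0, 0, 1), pt)
    expect_equal(rl, rp, tolerance = 1e-3)
  }
})

test_that("below-minimum radii are capped with a warning", {
  src <- cached_source()
  expect_warning(r <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(0.4, 0, 0)),
                 "below table minimum")
  ref <- dose_rate_at(src, c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(r, ref, tolerance = 1e-9)  # capped at r = 0.1 cm, transverse
})

test_that("dose accumulation: linearity, additivity and double-loop oracle", {
  case <- cached_phantom()
  paths <- cached_paths()
  src <- cached_source()
  dirs <- cached_dirs()
  sp <- sample_structure_points(case$contours$urethra, 2)
  pts <- sp$points

  d1 <- suppressWarnings(accumulate_dose(case, paths, src, pts, dirs = dirs))
  case2 <- case
  case2$dwells$times <- lapply(case$dwells$times, function(tt) tt * 2)
  d2 <- suppressWarnings(accumulate_dose(case2, paths, src, pts, dirs = dirs))
  expect_equal(d2$dose, 2 * d1$dose, tolerance = 1e-12)

  # additivity over a partition of the dwell set
  caseA <- case; caseA$dwells$times <- lapply(case$dwells$times,
                                              function(tt) { tt[1] <- 0; tt })
  caseB <- case; caseB$dwells$times <- lapply(case$dwells$times,
                                              function(tt) { tt[-1] <- 0; tt })
  dA <- suppressWarnings(accumulate_dose(caseA, paths, src, pts, dirs = dirs))
  dB <- suppressWarnings(accumulate_dose(caseB, paths, src, pts, dirs = dirs))
  expect_equal(dA$dose + dB$dose, d1$dose, tolerance = 1e-12)

  # two identical dwells of t equal one dwell of 2t
  dwx <- dwell_set(list(cbind(c(0, 0), c(0, 0), c(-3, -3))), list(c(5, 5)),
                   list(c(0, 0, 0)))
  dwy <- dwell_set(list(matrix(c(0, 0, -3), 1, 3)), list(10), list(c(0, 0, 0)))
  cx <- case_model(dwx, case$contours)
  cy <- case_model(dwy, case$contours)
  probe <- rbind(c(8, 2, -5), c(-6, 3, 1), c(0, 12, -3))
  ex <- accumulate_dose(cx, NULL, src, probe)
  ey <- accumulate_dose(cy, NULL, src, probe)
  expect_equal(ex$dose, ey$dose, tolerance = 1e-12)

  # naive double loop over dose_rate_at as an independent oracle
  pos <- do.call(rbind, case$dwells$positions)
  tms <- unlist(case$dwells$times)
  idx <- seq(1, nrow(pts), length.out = 9)
  oracle <- vapply(idx, function(p) {
    sum(vapply(seq_len(nrow(pos)), function(d)
      suppressWarnings(dose_rate_at(src, pos[d, ], dirs[d, ], pts[p, ])) *
        tms[d], numeric(1)))
  }, numeric(1))
  expect_equal(d1$dose[idx], oracle, tolerance = 1e-9)
})

test_that("dose is invariant under a global rigid translation", {
  case <- tiny_case(n_dwells = 3)
  src <- cached_source()
  pts <- rbind(c(5, 5, -2), c(-4, 8, -9), c(0, 2, 3))
  d0 <- accumulate_dose(case, NULL, src, pts)
  shift <- c(13, -7, 21)
  case2 <- case
  case2$dwells$positions <- lapply(case$dwells$positions,
                                   function(P) sweep(P, 2, shift, "+"))
  d1 <- accumulate_dose(case2, NULL, src, sweep(pts, 2, shift, "+"))
  expect_equal(d0$dose, d1$dose, tolerance = 1e-12)
})

test_that("source model validates and normalises its tables", {
  expect_error(source_model(1.1, 40000, 3.5,
                            data.frame(r_cm = c(2, 5), g = c(1, 0.9)),
                            list(r_cm = 1, theta_deg = 90,
                                 F = matrix(1, 1, 1))),
               "bracket")
  src <- flat_source()
  expect_equal(approx(log(src$radial_dose$r_cm), src$radial_dose$g,
                      xout = 0)$y, 1)
  an <- cached_source()$anisotropy
  i90 <- which(an$theta_deg == 90)
  expect_equal(unname(an$F[, i90]), rep(1, nrow(an$F)), tolerance = 1e-12)
})
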