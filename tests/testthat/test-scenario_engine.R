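test_that("quadrature combination reproduces the published budget totals", {
  expect_equal(round(combine_quadrature(c(1.1, 0.34, 1.0)), 1), 1.5)
  expect_equal(round(combine_quadrature(c(1.2, 0.86)), 1), 1.5)
  expect_equal(round(combine_quadrature(c(1, 3, 3)), 1), 4.4)
  expect_equal(combine_quadrature(c(3, 4)), 5)
  expect_error(combine_quadrature(numeric(0)), "empty")
  expect_error(combine_quadrature(c(1, -1)), ">= 0")

  b <- uncertainty_budget()
  expect_equal(round(b$p1_sd, 1), 1.5)
  expect_equal(round(b$p4_sd, 1), 1.5)
  expect_equal(round(b$p5_pct_sd, 1), 4.4)
})

test_that("probabilistic draws are truncated at 1.65 SD and recover the SD", {
  budget <- uncertainty_budget()
  set.seed(21)
  for (q in 1:200) {
    p <- sample_probabilistic(budget, 16)
    expect_lte(abs(p$p1_shift), 1.65 * budget$p1_sd)
    expect_lte(abs(p$p2_prostate), 1.65 * budget$p2_sd)
    expect_lte(abs(p$p3_urethra), 1.65 * budget$p3_urethra_sd)
    expect_lte(abs(p$p3_rectum), 1.65 * budget$p3_rectum_sd)
    expect_true(all(abs(p$p4_transverse) <= 1.65 * budget$p4_sd))
    expect_lte(abs(p$p5_scale - 1), 1.65 * budget$p5_pct_sd / 100)
    expect_lte(abs(p$p5_offset), 1.65 * budget$p5_offset_sd)
    expect_lte(abs(p$p6_rigid[1]), 1.65 * budget$p6_sd[["LR"]])
    expect_lte(abs(p$p6_rigid[2]), 1.65 * budget$p6_sd[["AP"]])
    expect_identical(p$p6_rigid[3], 0)  # SI budget is zero
  }

  # truncated-normal SD oracle by numerical integration
  a <- 1.65
  mass <- 2 * pnorm(a) - 1
  var_tr <- integrate(function(x) x^2 * dnorm(x), -a, a,
                      rel.tol = 1e-10)$value / mass
  sd_want <- 2.0 * sqrt(var_tr)   # prostate parameter, SD 2.0 mm
  set.seed(22)
  draws <- replicate(10000, sample_probabilistic(budget, 1)$p2_prostate)
  expect_equal(sd(draws), sd_want, tolerance = 0.03)
  expect_true(all(abs(draws) <= 1.65 * 2.0))

  # an all-zero budget yields all-zero draws
  zb <- uncertainty_budget(p1_components = 0, p2_sd = 0, p3_urethra_sd = 0,
                           p3_rectum_sd = 0, p4_components = 0,
                           p5_pct_components = 0, p5_offset_sd = 0,
                           p6_sd = c(LR = 0, AP = 0, SI = 0))
  pz <- sample_probabilistic(zb, 4)
  expect_equal(pz$p1_shift, 0)
  expect_equal(pz$p5_scale, 1)
  expect_true(all(pz$p4_transverse == 0))
})

test_that("worst-case enumeration is an exhaustive product of stated levels", {
  budget <- uncertainty_budget()
  case <- cached_phantom()
  wc <- enumerate_worst_case(budget, case)
  expect_length(wc, 3^5 * 4 * 2)  # the default composition documents 1944

  lv <- function(sd) c(-1.65 * sd, 0, 1.65 * sd)
  seen <- unique(t(vapply(wc, function(p)
    c(p$p1_shift, p$p2_prostate, p$p3_urethra, p$p3_rectum,
      p$p5_scale, p$p5_offset,
      if (is.null(p$p4_transverse)) c(0, 0) else p$p4_transverse[1, ],
      p$p6_rigid[2]),
    numeric(9))))
  expect_equal(nrow(seen), length(wc))  # all scenarios distinct

  # every scalar sits exactly at one of its levels (product oracle)
  oracle <- expand.grid(p1 = lv(budget$p1_sd), p2 = lv(budget$p2_sd),
                        p3u = lv(budget$p3_urethra_sd),
                        p3r = lv(budget$p3_rectum_sd),
                        s5 = c(-1, 0, 1))
  got_scalars <- unique(t(vapply(wc, function(p)
    c(p$p1_shift, p$p2_prostate, p$p3_urethra, p$p3_rectum,
      round((p$p5_scale - 1) * 100 / (1.65 * budget$p5_pct_sd), 9)),
    numeric(5))))
  expect_equal(nrow(got_scalars), nrow(oracle))

  # direction modes carry the coordinated geometry
  out_mode <- Filter(function(p) !is.null(p$p4_transverse), wc)[[1]]
  expect_equal(nrow(out_mode$p4_transverse), 16)
  mags <- sqrt(rowSums(out_mode$p4_transverse^2))
  expect_equal(mags, rep(1.65 * budget$p4_sd, 16), tolerance = 1e-9)

  # degenerate budget collapses to the single all-zero scenario
  zb <- uncertainty_budget(p1_components = 0, p2_sd = 0, p3_urethra_sd = 0,
                           p3_rectum_sd = 0, p4_components = 0,
                           p5_pct_components = 0, p5_offset_sd = 0,
                           p6_sd = c(LR = 0, AP = 0, SI = 0))
  wcz <- enumerate_worst_case(zb, case)
  expect_length(wcz, 1)
  expect_equal(wcz[[1]]$p1_shift, 0)
  expect_equal(wcz[[1]]$p5_scale, 1)
})

test_that("posterior worst-case mode moves every needle posterior only", {
  budget <- uncertainty_budget()
  case <- cached_phantom()
  v <- brachyrobust:::p4_mode_vectors(case, "posterior", 1.65 * budget$p4_sd)
  expect_equal(v[, 1], rep(0, 16))
  expect_equal(v[, 2], rep(1.65 * budget$p4_sd, 16))
  vin <- brachyrobust:::p4_mode_vectors(case, "in", 2)
  ctr <- brachyrobust:::prostate_centre_line(case)
  nc <- brachyrobust:::needle_transverse_centres(case)
  # "in" vectors point towards the prostate transverse centre line
  dots <- rowSums(vin * sweep(nc, 2, ctr))
  expect_true(all(dots < 0))
})

test_that("zero-parameter scenario reproduces nominal metrics", {
  case <- cached_phantom()
  paths <- cached_paths()
  src <- cached_source()
  a <- suppressWarnings(run_scenario(case, paths, src, scenario_params(),
                                     spacing = 2, curve_max = NULL))
  b <- suppressWarnings(run_scenario(case, paths, src, scenario_params(),
                                     spacing = 2, curve_max = NULL))
  expect_identical(a$metrics, b$metrics)
  expect_true(all(is.finite(a$metrics)))
  expect_true(all(a$metrics >= 0))

  set.seed(23)
  p <- sample_probabilistic(uncertainty_budget(), 16)
  r <- suppressWarnings(run_scenario(case, paths, src, p, spacing = 2,
                                     curve_max = NULL))
  expect_true(all(is.finite(r$metrics)))
  expect_true(all(r$metrics[c("V100", "V150", "V200")] <= 100))
})

test_that("run_evaluation is reproducible and summarises all metrics", {
  case <- cached_phantom()
  src <- cached_source()
  s1 <- run_evaluation(case, src, n_probabilistic = 2, seed = 99,
                       spacing = 2, curve_max = 40)
  s2 <- run_evaluation(case, src, n_probabilistic = 2, seed = 99,
                       spacing = 2, curve_max = 40)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$scenarios, s2$scenarios)
  expect_equal(nrow(s1$summary), 8)
  expect_setequal(s1$summary$metric, metric_names())
  expect_equal(s1$n_probabilistic, 2)
  expect_true(all(s1$sd_areas >= 0))
  expect_true(all(s1$summary$pass_rate >= 0 & s1$summary$pass_rate <= 1))

  s3 <- run_evaluation(case, src, n_probabilistic = 2, seed = 100,
                       spacing = 2, curve_max = 40)
  expect_false(identical(s1$scenarios, s3$scenarios))
})
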