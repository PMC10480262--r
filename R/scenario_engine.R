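# Scenario engine: the uncertainty budget, probabilistic sampling within the
# 90% confidence interval, worst-case enumeration at the +/- 1.65 SD limits,
# and the evaluation loop (perturb -> dose -> DVH -> summarise).

#' Uncertainty budget for the six variable parameters
#'
#' Defaults are the standard deviations of a TRUS-based single-fraction HDR
#' prostate workflow, obtained by quadrature combination of literature
#' uncertainty components: dwell shift along the needle (needle-tip
#' reconstruction 1.1 mm, rigid SI movement 0.34 mm, source positioning
#' 1.0 mm), prostate contour 2.0 mm, urethra contour 0.5 mm, rectum contour
#' 1.0 mm, transverse needle movement (reconstruction 1.2 mm, rigid 0.86 mm),
#' dwell-time percentage (medium corrections 1%, treatment planning 3%,
#' source activity 3%) with a 0.06 s timing offset, and rigid prostate motion
#' (AP 0.5 mm, LR 0.1 mm).  All values are user-configurable.
#'
#' @param p1_components named numeric, mm; combined in quadrature.
#' @param p2_sd prostate boundary SD, mm.
#' @param p3_urethra_sd,p3_rectum_sd slice-wise contour SDs, mm.
#' @param p4_components named numeric, mm; combined in quadrature (applies
#'   independently per needle per transverse axis).
#' @param p5_pct_components named numeric, percent; combined in quadrature.
#' @param p5_offset_sd dwell-time offset SD, s.
#' @param p6_sd named numeric `c(LR =, AP =, SI =)`, mm.
#' @return object of class `uncertainty_budget` with component vectors and
#'   quadrature totals `p1_sd`, `p4_sd`, `p5_pct_sd`.
#' @export
uncertainty_budget <- function(
    p1_components = c(reconstruction = 1.1, rigid = 0.34, source = 1.0),
    p2_sd = 2.0,
    p3_urethra_sd = 0.5,
    p3_rectum_sd = 1.0,
    p4_components = c(reconstruction = 1.2, rigid = 0.86),
    p5_pct_components = c(medium = 1, planning = 3, activity = 3),
    p5_offset_sd = 0.06,
    p6_sd = c(LR = 0.1, AP = 0.5, SI = 0)) {
  b <- list(p1_components = p1_components,
            p1_sd = combine_quadrature(p1_components),
            p2_sd = p2_sd,
            p3_urethra_sd = p3_urethra_sd,
            p3_rectum_sd = p3_rectum_sd,
            p4_components = p4_components,
            p4_sd = combine_quadrature(p4_components),
            p5_pct_components = p5_pct_components,
            p5_pct_sd = combine_quadrature(p5_pct_components),
            p5_offset_sd = p5_offset_sd,
            p6_sd = p6_sd)
  sds <- c(b$p1_sd, b$p2_sd, b$p3_urethra_sd, b$p3_rectum_sd, b$p4_sd,
           b$p5_pct_sd, b$p5_offset_sd, b$p6_sd)
  if (any(sds < 0)) stop("uncertainty_budget: standard deviations must be >= 0")
  structure(b, class = "uncertainty_budget")
}

# zero-mean normal truncated at +/- trunc*sd (hard rejection)
rtruncnorm_sd <- function(n, sd, trunc = 1.65) {
  if (sd == 0 || n == 0) return(rep(0, n))
  out <- stats::rnorm(n, 0, sd)
  bad <- abs(out) > trunc * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(out) > trunc * sd
  }
  out
}

#' Draw one probabilistic scenario from the budget
#'
#' Every scalar is drawn from a zero-mean normal with the budget SD, hard
#' truncated at +/- 1.65 SD (the 90% confidence interval); the transverse
#' needle movement is drawn independently per needle and axis.  The
#' dwell-time percentage becomes the multiplier `1 + pct/100`.  Uses the
#' current R random stream; seed externally for reproducibility.
#'
#' @param budget an [uncertainty_budget()].
#' @param n_needles number of needles in the plan.
#' @param trunc truncation limit in SD multiples (default 1.65).
#' @return a [scenario_params()].
#' @export
sample_probabilistic <- function(budget, n_needles, trunc = 1.65) {
  stopifnot(inherits(budget, "uncertainty_budget"), n_needles >= 1)
  p1 <- rtruncnorm_sd(1, budget$p1_sd, trunc)
  p2 <- rtruncnorm_sd(1, budget$p2_sd, trunc)
  p3u <- rtruncnorm_sd(1, budget$p3_urethra_sd, trunc)
  p3r <- rtruncnorm_sd(1, budget$p3_rectum_sd, trunc)
  p4 <- cbind(rtruncnorm_sd(n_needles, budget$p4_sd, trunc),
              rtruncnorm_sd(n_needles, budget$p4_sd, trunc))
  pct <- rtruncnorm_sd(1, budget$p5_pct_sd, trunc)
  off <- rtruncnorm_sd(1, budget$p5_offset_sd, trunc)
  p6 <- c(rtruncnorm_sd(1, budget$p6_sd[["LR"]], trunc),
          rtruncnorm_sd(1, budget$p6_sd[["AP"]], trunc),
          rtruncnorm_sd(1, budget$p6_sd[["SI"]], trunc))
  scenario_params(p1_shift = p1, p2_prostate = p2, p3_urethra = p3u,
                  p3_rectum = p3r, p4_transverse = p4,
                  p5_scale = 1 + pct / 100, p5_offset = off, p6_rigid = p6)
}

# transverse needle centres and the prostate transverse centre line
needle_transverse_centres <- function(case) {
  t(vapply(case$dwells$positions, function(P) colMeans(P[, 1:2, drop = FALSE]),
           numeric(2)))
}

prostate_centre_line <- function(case) {
  V <- all_vertices(case$contours$prostate)
  colMeans(V[, 1:2, drop = FALSE])
}

# coordinated per-needle transverse vectors for a worst-case direction mode
p4_mode_vectors <- function(case, mode, magnitude) {
  n <- n_needles(case$dwells)
  if (mode == "none" || magnitude == 0) return(NULL)
  if (mode == "posterior")
    return(cbind(rep(0, n), rep(magnitude, n)))
  ctr <- prostate_centre_line(case)
  nc <- needle_transverse_centres(case)
  rel <- sweep(nc, 2, ctr)
  nrm <- sqrt(rowSums(rel^2))
  nrm[nrm < 1e-9] <- 1
  u <- rel / nrm
  if (mode == "out") u * magnitude else if (mode == "in") -u * magnitude
  else stop("p4_mode_vectors: unknown mode ", mode)
}

#' Enumerate the worst-case scenario set
#'
#' Scalar parameters (dwell shift, prostate boundary, urethra and rectum
#' contours, and the joint dwell-time percentage/offset) take each of the
#' levels `{-1.65 SD, 0, +1.65 SD}` in a full factorial; these are crossed
#' with coordinated transverse-needle direction modes (`none`, all needles
#' radially `out` from / `in` towards the prostate transverse centre line,
#' all needles `posterior`) at the 1.65 SD magnitude, and with the two signs
#' of the rigid-motion budget vector.  Degenerate (zero-SD) parameters
#' collapse to the single zero level, so an all-zero budget yields exactly
#' one all-zero scenario.  With the default budget the enumeration yields
#' 3^5 x 4 x 2 = 1944 scenarios.  Deterministic order.
#'
#' @param budget an [uncertainty_budget()].
#' @param case the nominal [case_model()] (for needle/prostate geometry).
#' @param modes transverse direction modes to include.
#' @param trunc limit in SD multiples (default 1.65).
#' @return list of [scenario_params()].
#' @export
enumerate_worst_case <- function(budget, case,
                                 modes = c("none", "out", "in", "posterior"),
                                 trunc = 1.65) {
  stopifnot(inherits(budget, "uncertainty_budget"), inherits(case, "case_model"))
  lv <- function(sd) if (sd == 0) 0 else c(-trunc * sd, 0, trunc * sd)
  l1 <- lv(budget$p1_sd); l2 <- lv(budget$p2_sd)
  l3u <- lv(budget$p3_urethra_sd); l3r <- lv(budget$p3_rectum_sd)
  # p5 percentage and offset vary jointly (same sign at the limits)
  l5 <- if (budget$p5_pct_sd == 0 && budget$p5_offset_sd == 0) 0 else c(-1, 0, 1)
  if (budget$p4_sd == 0) modes <- "none"
  modes <- unique(modes)
  p6v <- trunc * c(budget$p6_sd[["LR"]], budget$p6_sd[["AP"]], budget$p6_sd[["SI"]])
  l6 <- if (all(p6v == 0)) list(c(0, 0, 0)) else list(p6v, -p6v)
  grid <- expand.grid(i1 = seq_along(l1), i2 = seq_along(l2),
                      i3u = seq_along(l3u), i3r = seq_along(l3r),
                      i5 = seq_along(l5), im = seq_along(modes),
                      i6 = seq_along(l6))
  mag4 <- trunc * budget$p4_sd
  lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    s5 <- l5[g$i5]
    scenario_params(
      p1_shift = l1[g$i1], p2_prostate = l2[g$i2],
      p3_urethra = l3u[g$i3u], p3_rectum = l3r[g$i3r],
      p4_transverse = p4_mode_vectors(case, modes[g$im], mag4),
      p5_scale = 1 + s5 * trunc * budget$p5_pct_sd / 100,
      p5_offset = s5 * trunc * budget$p5_offset_sd,
      p6_rigid = l6[[g$i6]])
  })
}

#' Evaluate one scenario: perturb, dose, DVH, metrics
#'
#' @param case nominal [case_model()].
#' @param paths `needle_paths` built from the nominal dwells.
#' @param source a `source_model`.
#' @param params a [scenario_params()].
#' @param spacing dose-point grid spacing, mm.
#' @param bin_width DVH bin width, Gy.
#' @param curve_max top of the common DVH dose grid, Gy; NULL to skip curves.
#' @param dirs optional precomputed source-axis matrix from
#'   [dwell_directions()] on the nominal plan (source orientation is assumed
#'   unchanged by the perturbations).
#' @return list with `metrics` (named vector), `constraints` (from
#'   [evaluate_constraints()]), and per-structure `curves` (relative-volume
#'   vectors on the common grid) when requested.
#' @export
run_scenario <- function(case, paths, source, params, spacing = 1,
                         bin_width = 0.01, curve_max = 40, dirs = NULL) {
  scen <- apply_scenario(case, paths, params)
  if (is.null(dirs)) dirs <- dwell_directions(case$dwells, paths)
  doses <- list(); curves <- list()
  for (nm in STRUCTURE_NAMES) {
    sp <- sample_structure_points(scen$contours[[nm]], spacing)
    ds <- accumulate_dose(scen, paths, source, sp$points, sp$weight, dirs)
    doses[[nm]] <- list(dose = ds$dose, weight = ds$weight)
    if (!is.null(curve_max))
      curves[[nm]] <- compute_dvh(ds$dose, ds$weight, bin_width,
                                  max_dose = curve_max)$rel_volume
  }
  metrics <- compute_metrics(doses, scen$prescription)
  list(metrics = metrics,
       constraints = evaluate_constraints(metrics, scen$constraints),
       curves = if (is.null(curve_max)) NULL else curves)
}

#' Run the full robust evaluation
#'
#' Evaluates the nominal plan, `n_probabilistic` sampled scenarios and
#' (optionally) the enumerated worst-case set, and summarises the DVH-metric
#' ensemble: mean, SD, quartiles, SEM 95% CI, skewness, per-constraint and
#' overall pass rates, worst-case extrema, and the per-structure SD-per-dose
#' area.  Fully reproducible given `seed`.
#'
#' @param case nominal [case_model()].
#' @param source a `source_model` (default [default_source()]).
#' @param n_probabilistic number of probabilistic scenarios (>= 1).
#' @param seed integer seed for the scenario stream.
#' @param worst_case evaluate the enumerated worst-case set as well.
#' @param budget an [uncertainty_budget()].
#' @param spacing dose-point grid spacing, mm.
#' @param bin_width DVH bin width, Gy.
#' @param curve_max top of the common DVH dose grid, Gy.
#' @param modes worst-case transverse direction modes.
#' @param progress print a line every `progress` scenarios (0 = quiet).
#' @return object of class `robust_summary`; see Details.  The per-scenario
#'   metric table is in `$scenarios`, the summary table in `$summary`.
#' @export
run_evaluation <- function(case, source = default_source(),
                           n_probabilistic = 1000, seed = 1,
                           worst_case = FALSE, budget = uncertainty_budget(),
                           spacing = 1, bin_width = 0.01,
                           curve_max = 40,
                           modes = c("none", "out", "in", "posterior"),
                           progress = 0) {
  stopifnot(inherits(case, "case_model"), n_probabilistic >= 1,
            inherits(budget, "uncertainty_budget"))
  paths <- build_needle_paths(case$dwells)
  dirs <- dwell_directions(case$dwells, paths)
  nn <- n_needles(case$dwells)
  t0 <- proc.time()[["elapsed"]]

  nominal <- suppressWarnings(
    run_scenario(case, paths, source, scenario_params(), spacing, bin_width,
                 curve_max, dirs))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- lapply(seq_len(n_probabilistic), function(i)
    sample_probabilistic(budget, nn))

  nbins <- length(seq(0, curve_max, by = bin_width))
  pr_curves <- lapply(STRUCTURE_NAMES, function(nm)
    matrix(NA_real_, n_probabilistic, nbins))
  names(pr_curves) <- STRUCTURE_NAMES
  rows <- vector("list", n_probabilistic)
  n_failed <- 0L
  for (i in seq_len(n_probabilistic)) {
    res <- tryCatch(
      suppressWarnings(run_scenario(case, paths, source, draws[[i]], spacing,
                                    bin_width, curve_max, dirs)),
      error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    for (nm in STRUCTURE_NAMES) pr_curves[[nm]][i, ] <- res$curves[[nm]]
    rows[[i]] <- c(scenario = i, res$metrics, as.numeric(res$constraints$pass))
    if (progress > 0 && i %% progress == 0)
      message(sprintf("probabilistic %d/%d (%.1f s elapsed)", i,
                      n_probabilistic, proc.time()[["elapsed"]] - t0))
  }
  ok <- !vapply(rows, is.null, logical(1))
  tab <- as.data.frame(do.call(rbind, rows[ok]))
  names(tab) <- c("scenario", metric_names(), paste0("pass_", metric_names()))
  tab$type <- "probabilistic"
  for (nm in STRUCTURE_NAMES) pr_curves[[nm]] <- pr_curves[[nm]][ok, , drop = FALSE]

  wc_tab <- NULL; wc_env <- NULL; wc_n <- 0L
  if (worst_case) {
    wc_params <- enumerate_worst_case(budget, case, modes = modes)
    wc_n <- length(wc_params)
    wc_rows <- vector("list", wc_n)
    wc_env <- lapply(STRUCTURE_NAMES, function(nm)
      list(lo = rep(Inf, nbins), hi = rep(-Inf, nbins)))
    names(wc_env) <- STRUCTURE_NAMES
    for (i in seq_len(wc_n)) {
      res <- tryCatch(
        suppressWarnings(run_scenario(case, paths, source, wc_params[[i]],
                                      spacing, bin_width, curve_max, dirs)),
        error = function(e) e)
      if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
      for (nm in STRUCTURE_NAMES) {
        wc_env[[nm]]$lo <- pmin(wc_env[[nm]]$lo, res$curves[[nm]])
        wc_env[[nm]]$hi <- pmax(wc_env[[nm]]$hi, res$curves[[nm]])
      }
      wc_rows[[i]] <- c(scenario = i, res$metrics,
                        as.numeric(res$constraints$pass))
      if (progress > 0 && i %% progress == 0)
        message(sprintf("worst-case %d/%d (%.1f s elapsed)", i, wc_n,
                        proc.time()[["elapsed"]] - t0))
    }
    okw <- !vapply(wc_rows, is.null, logical(1))
    wc_tab <- as.data.frame(do.call(rbind, wc_rows[okw]))
    names(wc_tab) <- names(tab)[names(tab) != "type"]
    wc_tab$type <- "worst_case"
  }

  mt <- metric_names()
  summary_tab <- do.call(rbind, lapply(mt, function(m) {
    v <- tab[[m]]
    ci <- mean_ci_sem(v)
    data.frame(metric = m, nominal = unname(nominal$metrics[m]),
               mean = mean(v), sd = stats::sd(v),
               q1 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q3 = unname(stats::quantile(v, 0.75)),
               ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
               skewness = tryCatch(skewness_fp(v), error = function(e) NA_real_),
               n_pass = sum(tab[[paste0("pass_", m)]]),
               pass_rate = mean(tab[[paste0("pass_", m)]]),
               wc_min = if (is.null(wc_tab)) NA_real_ else min(wc_tab[[m]]),
               wc_max = if (is.null(wc_tab)) NA_real_ else max(wc_tab[[m]]),
               stringsAsFactors = FALSE)
  }))
  pr_flags <- tab[, paste0("pass_", mt)] == 1
  colnames(pr_flags) <- mt
  rates <- pass_rates(pr_flags)
  areas <- vapply(STRUCTURE_NAMES, function(nm)
    sd_area(pr_curves[[nm]], bin_width), numeric(1))

  structure(list(
    summary = summary_tab,
    scenarios = rbind(tab, wc_tab),
    pass_rates = rates,
    sd_areas = areas,
    nominal = nominal,
    curves = list(dose_bins = seq(0, curve_max, by = bin_width),
                  probabilistic = pr_curves, worst_case_envelope = wc_env,
                  nominal = nominal$curves),
    n_probabilistic = sum(ok), n_worst_case = wc_n, n_failed = n_failed,
    seed = seed, spacing = spacing, bin_width = bin_width,
    elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "robust_summary")
}

#' @export
print.robust_summary <- function(x, ...) {
  cat(sprintf("<robust_summary> %d probabilistic + %d worst-case scenarios (%.1f s)\n",
              x$n_probabilistic, x$n_worst_case, x$elapsed_s))
  df <- x$summary
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 2) else v)
  print(df, row.names = FALSE)
  cat(sprintf("pass rate all constraints: %.1f%%; excluding V200: %.1f%%\n",
              100 * x$pass_rates$all, 100 * x$pass_rates$all_excluding))
  cat(sprintf("SD-per-dose areas (Gy): prostate %.2f, urethra %.2f, rectum %.2f\n",
              x$sd_areas[["prostate"]], x$sd_areas[["urethra"]],
              x$sd_areas[["rectum"]]))
  invisible(x)
}
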