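# Statistical summaries of scenario ensembles: SEM-based confidence
# intervals, normal tail probability, Fisher-Pearson skewness, bootstrap
# percentile CI of the median, one-tailed one-sample t-test, constraint
# pass rates and the SD-per-dose robustness area.

#' Combine uncertainty components in quadrature
#'
#' Square root of the sum of squared standard deviations; rounding is a
#' display concern only.
#'
#' @param components numeric vector of component SDs (all >= 0).
#' @return total SD.
#' @export
combine_quadrature <- function(components) {
  if (length(components) == 0L) stop("combine_quadrature: empty component list")
  if (any(components < 0)) stop("combine_quadrature: components must be >= 0")
  sqrt(sum(components^2))
}

#' Mean with SEM-based normal confidence interval
#'
#' `mean +/- z * SD / sqrt(n)` with the normal quantile (z = 1.96 at 95%),
#' appropriate for the large scenario ensembles used here.
#'
#' @param values numeric vector (n >= 2).
#' @param level confidence level (default 0.95).
#' @return named vector (mean, lower, upper).
#' @export
mean_ci_sem <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("mean_ci_sem: need at least 2 values")
  mean_ci_sem_from_summary(mean(values), stats::sd(values), n, level)
}

#' SEM confidence interval from printed summary statistics
#'
#' @param mean,sd,n summary statistics of the ensemble.
#' @param level confidence level.
#' @return named vector (mean, lower, upper).
#' @export
mean_ci_sem_from_summary <- function(mean, sd, n, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sd / sqrt(n)
  c(mean = mean, lower = mean - half, upper = mean + half)
}

#' One-sided standard-normal tail probability
#'
#' Probability of a draw at `z_limit` standard deviations or more extreme on
#' one side; 0.05 at the 1.65 SD truncation limit used for the 90% CI.
#'
#' @param z_limit SD multiple (>= 0).
#' @return upper-tail probability.
#' @export
tail_probability <- function(z_limit) {
  stopifnot(z_limit >= 0)
  stats::pnorm(z_limit, lower.tail = FALSE)
}

#' Fisher-Pearson coefficient of skewness
#'
#' The standardised third central moment g1 (`adjusted = FALSE`, default) or
#' the adjusted coefficient G1.
#'
#' @param values numeric vector (n >= 3, nonzero variance).
#' @param adjusted use the adjusted (sample-size corrected) variant.
#' @return skewness coefficient.
#' @export
skewness_fp <- function(values, adjusted = FALSE) {
  if (length(values) < 3L) stop("skewness_fp: need at least 3 values")
  if (stats::sd(values) == 0) stop("skewness_fp: zero variance")
  e1071::skewness(values, type = if (adjusted) 2L else 1L)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples the data with replacement `n_boot` times, computes the
#' statistic on each resample, and returns order statistics of the bootstrap
#' distribution as the percentile interval (Efron's (B+1)*alpha rule,
#' clamped to the achievable range).
#'
#' @param values numeric vector (n >= 2).
#' @param statistic function of a numeric vector (default [median()]).
#' @param n_boot number of bootstrap resamples (>= 100, default 1000).
#' @param level confidence level.
#' @param seed integer seed for reproducibility.
#' @return named vector (lower, upper).
#' @export
bootstrap_percentile_ci <- function(values, statistic = stats::median,
                                    n_boot = 1000, level = 0.95, seed = 1) {
  n <- length(values)
  if (n < 2L) stop("bootstrap_percentile_ci: need at least 2 values")
  if (n_boot < 100L) stop("bootstrap_percentile_ci: n_boot must be >= 100")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats_boot <- vapply(seq_len(n_boot), function(b)
    statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  s <- sort(stats_boot)
  alpha <- (1 - level) / 2
  lo <- min(max(floor((n_boot + 1) * alpha), 1L), n_boot)
  hi <- max(min(ceiling((n_boot + 1) * (1 - alpha)), n_boot), 1L)
  c(lower = s[lo], upper = s[hi])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' One-sample one-tailed t-test
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @param mu0 null-hypothesis mean.
#' @param direction `"greater"` or `"less"`: the alternative hypothesis.
#' @return named vector (t, p).
#' @export
one_tail_t <- function(values, mu0, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) stop("one_tail_t: need at least 2 values")
  if (stats::sd(values) == 0) stop("one_tail_t: zero variance")
  tt <- stats::t.test(values, mu = mu0, alternative = direction)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' SD-per-dose robustness area of a DVH ensemble
#'
#' Per dose bin, the standard deviation of relative volume across the
#' scenario ensemble; the area is the sum of SDs times the bin width (Gy),
#' a whole-curve measure of the plan's sensitivity to uncertainty for one
#' structure.
#'
#' @param curves matrix of relative volumes, one row per scenario, columns on
#'   a common uniform dose grid.
#' @param bin_width dose bin width of the grid, Gy.
#' @return area in Gy.
#' @export
sd_area <- function(curves, bin_width) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2L) stop("sd_area: need at least 2 curves")
  sds <- apply(curves, 2, stats::sd)
  sum(sds) * bin_width
}

#' Constraint pass rates over a scenario ensemble
#'
#' @param flags logical matrix or data.frame, one row per scenario, one
#'   column per constraint (column names are the metric names).
#' @param exclude metric excluded from the secondary overall rate (default
#'   `"V200"`).
#' @return list with `per_constraint` (named rates), `all` and
#'   `all_excluding` overall rates.
#' @export
pass_rates <- function(flags, exclude = "V200") {
  flags <- as.matrix(flags)
  if (nrow(flags) < 1L) stop("pass_rates: need at least one scenario")
  per <- colMeans(flags)
  keep <- colnames(flags)[!colnames(flags) %in% exclude]
  list(per_constraint = per,
       all = mean(rowSums(!flags) == 0),
       all_excluding = mean(rowSums(!flags[, keep, drop = FALSE]) == 0))
}
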