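#' Paired test-retest estimates
#'
#' Light validation helper: checks two equal-length vectors of paired
#' estimates over units (voxels or tract segments).
#'
#' @param test,retest Numeric vectors of paired estimates.
#' @return Invisibly, a tibble with columns `test`, `retest`.
#' @keywords internal
check_pair <- function(test, retest) {
  if (length(test) != length(retest) || length(test) < 2) {
    stop("test and retest must be paired vectors of length >= 2", call. = FALSE)
  }
  if (any(!is.finite(test)) || any(!is.finite(retest))) {
    stop("paired estimates must be finite", call. = FALSE)
  }
  tibble::tibble(test = test, retest = retest)
}

#' Test-retest variability
#'
#' \deqn{{\rm TRV} = \sqrt{\pi/2}\;\frac{1}{N}\sum_i
#'   \frac{|\Delta\theta(x_i)|}{\mu_\theta(x_i)},}
#' the mean absolute test-retest difference normalised by the pair mean,
#' scaled by \eqn{\sqrt{\pi/2}} so that under Gaussian repeats with
#' per-measurement coefficient of variation c, TRV converges to
#' \eqn{\sqrt 2\, c}. Reported in percent.
#'
#' @param test,retest Paired estimate vectors.
#' @return TRV in percent.
#' @export
#' @examples
#' trv(c(1, 2), c(1.2, 1.8)) # 17.99
trv <- function(test, retest) {
  pair <- check_pair(test, retest)
  mu <- (pair$test + pair$retest) / 2
  if (any(mu == 0)) {
    stop(sprintf("zero pair mean at unit(s): %s",
                 paste(which(mu == 0), collapse = ", ")), call. = FALSE)
  }
  100 * sqrt(pi / 2) * mean(abs(pair$test - pair$retest) / mu)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects, single-measurement, absolute-agreement
#' intraclass correlation from the two-way ANOVA mean squares:
#' \deqn{{\rm ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 sessions and n units, with the F-based 95% confidence
#' interval of McGraw & Wong. The qualitative band (poor < 0.5, moderate
#' 0.5-0.75, good 0.75-0.9, excellent > 0.9) is reported for the point
#' estimate and for the CI lower bound.
#'
#' @param test,retest Paired estimate vectors (n >= 3).
#' @param conf_level Confidence level for the interval.
#' @return Tibble with `icc`, `ci_lower`, `ci_upper`, `band`,
#'   `band_lower`, `n`, `undefined` (TRUE when between-unit variance
#'   vanishes).
#' @export
icc_a1 <- function(test, retest, conf_level = 0.95) {
  pair <- check_pair(test, retest)
  n <- nrow(pair)
  if (n < 3) stop("ICC needs at least 3 units", call. = FALSE)
  k <- 2
  Y <- cbind(pair$test, pair$retest)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  grand <- mean(Y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((Y - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  undefined <- msr <= .Machine$double.eps * grand^2
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lo <- hi <- icc
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  band_of <- function(x) {
    if (!is.finite(x)) return(NA_character_)
    if (x < 0.5) "poor" else if (x < 0.75) "moderate"
    else if (x <= 0.9) "good" else "excellent"
  }
  tibble::tibble(icc = icc, ci_lower = lo, ci_upper = hi,
                 band = band_of(icc), band_lower = band_of(lo), n = n,
                 undefined = undefined)
}

#' Bland-Altman agreement summary
#'
#' Percentage differences (retest minus test, normalised by the pair mean,
#' x 100), their mean and standard deviation, and the +/- 1.96 SD limits
#' of agreement about the mean difference.
#'
#' @param test,retest Paired estimate vectors.
#' @return Tibble with `mean_diff_pct`, `sd_diff_pct`, `loa_lower`,
#'   `loa_upper`, `n`, and a `differences` list-column.
#' @export
bland_altman <- function(test, retest) {
  pair <- check_pair(test, retest)
  mu <- (pair$test + pair$retest) / 2
  if (any(mu == 0)) {
    stop(sprintf("zero pair mean at unit(s): %s",
                 paste(which(mu == 0), collapse = ", ")), call. = FALSE)
  }
  d <- 100 * (pair$retest - pair$test) / mu
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  tibble::tibble(mean_diff_pct = m, sd_diff_pct = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 n = length(d), differences = list(d))
}

#' Default biophysical plausibility bounds
#'
#' Screening ranges applied before the between-metric correlation
#' analysis: fractional anisotropy in `[0, 1]`, diffusivities in `[0, 4]`
#' um^2/ms, kurtosis metrics in `[-1, 10]`; unlisted metrics are not
#' screened.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
plausibility_bounds <- function() {
  list(fa = c(0, 1), md = c(0, 4), ad = c(0, 4), rd = c(0, 4),
       mk = c(-1, 10), ak = c(-1, 10), rk = c(-1, 10))
}

#' Pearson correlation matrix across diffusion metrics
#'
#' Computes all pairwise Pearson correlations between per-voxel metric
#' columns after listwise exclusion of voxels failing any plausibility
#' bound (or containing non-finite values).
#'
#' @param metrics Data frame / tibble, one row per voxel, one column per
#'   metric.
#' @param bounds Named list of `c(lower, upper)` bounds
#'   (default [plausibility_bounds()]); names are matched to columns.
#' @return Symmetric correlation matrix of class `metric_cor` with unit
#'   diagonal; attributes `n_used` and `excluded` (per-bound exclusion
#'   counts).
#' @export
correlation_matrix <- function(metrics, bounds = plausibility_bounds()) {
  metrics <- tibble::as_tibble(metrics)
  if (ncol(metrics) < 2) stop("need at least two metrics", call. = FALSE)
  keep <- rep(TRUE, nrow(metrics))
  excluded <- integer(0)
  for (nm in names(metrics)) {
    bad <- !is.finite(metrics[[nm]])
    if (nm %in% names(bounds)) {
      b <- bounds[[nm]]
      bad <- bad | metrics[[nm]] < b[1] | metrics[[nm]] > b[2]
    }
    excluded[nm] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (sum(keep) < 3) {
    stop(paste0("fewer than 3 voxels pass the plausibility screen; ",
                "exclusions: ",
                paste(names(excluded), excluded, sep = "=", collapse = ", ")),
         call. = FALSE)
  }
  m <- cor(as.matrix(metrics[keep, ]))
  diag(m) <- 1
  attr(m, "n_used") <- sum(keep)
  attr(m, "excluded") <- excluded
  class(m) <- c("metric_cor", class(m))
  m
}

#' Tract-density percentile mask
#'
#' Retains voxels whose tract density is at or above the p-th percentile
#' of the nonzero densities (ties retained). `p = 0` keeps every nonzero
#' voxel.
#'
#' @param density Numeric vector or array of tract densities (>= 0).
#' @param p Percentile in `[0, 100)`.
#' @return Logical mask of the same shape.
#' @export
density_mask <- function(density, p = 75) {
  if (any(density < 0, na.rm = TRUE)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  nz <- density[density > 0 & is.finite(density)]
  if (length(nz) == 0) return(density > 0)
  thr <- quantile(nz, p / 100, names = FALSE)
  mask <- density >= thr & density > 0
  mask[!is.finite(density)] <- FALSE
  mask
}

#' Power of a two-sample t-test from a test-retest variability
#'
#' Converts a test-retest variability into a per-measurement coefficient
#' of variation (CV = TRV/sqrt(2), the exact Gaussian-repeats consequence
#' of the folded-normal TRV definition), forms Cohen's d =
#' diff_pct / CV_pct, and evaluates the exact noncentral-t power of a
#' two-sided (or one-sided) two-sample t-test with `n_total/2` subjects
#' per group.
#'
#' @param diff_pct Percentage difference between cohort means (>= 0).
#' @param trv_pct Test-retest variability, percent (> 0).
#' @param n_total Total sample size (even, >= 4), split equally.
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_two_sample(18, 10, 14)
power_two_sample <- function(diff_pct, trv_pct, n_total, alpha = 0.05,
                             tails = 2) {
  if (trv_pct <= 0) stop("trv_pct must be positive", call. = FALSE)
  stopifnot(diff_pct >= 0, n_total >= 4, n_total %% 2 == 0, tails %in% 1:2)
  cv_pct <- trv_pct / sqrt(2)
  d <- diff_pct / cv_pct
  n <- n_total / 2
  ncp <- d * sqrt(n / 2)
  df <- n_total - 2
  # pt() warns about its last 1e-8 of tail precision at large ncp; that is
  # far below any tolerance used here
  if (tails == 2) {
    tcrit <- qt(1 - alpha / 2, df)
    suppressWarnings((1 - pt(tcrit, df, ncp)) + pt(-tcrit, df, ncp))
  } else {
    tcrit <- qt(1 - alpha, df)
    suppressWarnings(1 - pt(tcrit, df, ncp))
  }
}

#' Smallest even total sample size reaching a target power
#'
#' @inheritParams power_two_sample
#' @param target_power Required power.
#' @param n_max Search ceiling.
#' @return Smallest even `n_total` with power >= `target_power`.
#' @export
required_n <- function(diff_pct, trv_pct, target_power = 0.96, alpha = 0.05,
                       tails = 2, n_max = 10000) {
  for (n in seq(4, n_max, by = 2)) {
    if (power_two_sample(diff_pct, trv_pct, n, alpha, tails) >= target_power) {
      return(n)
    }
  }
  stop("target power not reached below n_max", call. = FALSE)
}

#' Reliability report for one metric
#'
#' Bundles the paired statistics the test-retest analysis reports: TRV,
#' ICC(A,1) with confidence interval and interpretation band, and the
#' Bland-Altman summary.
#'
#' @param test,retest Paired estimate vectors.
#' @param metric Metric name carried in the output.
#' @return Object of class `reliability_report`.
#' @export
reliability_report <- function(test, retest, metric = "metric") {
  structure(list(metric = metric, n = length(test),
                 trv = trv(test, retest),
                 icc = icc_a1(test, retest),
                 bland_altman = bland_altman(test, retest)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s over %d units\n", x$metric, x$n))
  cat(sprintf("  TRV  %.2f%%\n", x$trv))
  cat(sprintf("  ICC  %.3f [%.3f, %.3f] (%s)\n", x$icc$icc, x$icc$ci_lower,
              x$icc$ci_upper, x$icc$band))
  cat(sprintf("  B-A  mean %.2f%%, LoA [%.2f, %.2f]%%\n",
              x$bland_altman$mean_diff_pct, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  invisible(x)
}
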