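#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a radius fit
#'
#' @param x A `radius_fit` from [fit_radius()].
#' @param ... Unused.
#' @return One-row tibble with the estimates, their Cramer-Rao standard
#'   deviations (when available) and flags.
#' @exportS3Method generics::tidy
#' @export
tidy.radius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "r"),
    estimate = c(x$beta, x$r),
    crlb_sd = c(x$crlb_sd_beta, x$crlb_sd_r)
  )
}

#' @rdname tidy.radius_fit
#' @exportS3Method generics::glance
#' @export
glance.radius_fit <- function(x, ...) {
  tibble::tibble(r = x$r, beta = x$beta, residual_norm = x$residual_norm,
                 n_shells = x$n_shells, converged = x$converged,
                 at_resolution_limit = x$at_resolution_limit)
}

#' Tidy a reliability report
#'
#' @param x A `reliability_report`.
#' @param ... Unused.
#' @return One-row-per-statistic tibble (TRV, ICC with CI, Bland-Altman
#'   mean difference and limits of agreement).
#' @exportS3Method generics::tidy
#' @export
tidy.reliability_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("trv_pct", "icc", "icc_ci_lower", "icc_ci_upper",
                  "ba_mean_diff_pct", "ba_loa_lower", "ba_loa_upper"),
    value = c(x$trv, x$icc$icc, x$icc$ci_lower, x$icc$ci_upper,
              x$bland_altman$mean_diff_pct, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper)
  )
}

#' @rdname tidy.reliability_report
#' @exportS3Method generics::glance
#' @export
glance.reliability_report <- function(x, ...) {
  tibble::tibble(metric = x$metric, n = x$n, trv_pct = x$trv,
                 icc = x$icc$icc, icc_band = x$icc$band,
                 ba_mean_diff_pct = x$bland_altman$mean_diff_pct)
}

#' Tidy a metric correlation matrix
#'
#' @param x A `metric_cor` matrix from [correlation_matrix()].
#' @param ... Unused.
#' @return Long tibble with columns `metric1`, `metric2`, `rho`.
#' @exportS3Method generics::tidy
#' @export
tidy.metric_cor <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n_used") <- NULL
  attr(m, "excluded") <- NULL
  tibble::as_tibble(as.table(m), .name_repair = "minimal") |>
    setNames(c("metric1", "metric2", "rho"))
}
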