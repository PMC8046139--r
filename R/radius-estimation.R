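#' Estimate the effective MR radius from strong-shell spherical means
#'
#' Fits the powder-average model \eqn{\bar S(b) = \beta b^{-1/2}
#' S_\perp(r)} to per-shell spherical means acquired at b >= 6 ms/um^2.
#' Working on \eqn{y = \bar S \sqrt b} decouples the nuisance amplitude:
#' with exactly two shells the ratio \eqn{y_{\rm high}/y_{\rm low} =
#' \exp[\ln S_\perp(r; {\rm high}) - \ln S_\perp(r; {\rm low})]} depends on
#' `r` alone and is strictly decreasing, so the fit reduces to a bracketing
#' root solve on `[0, r_max]` with \eqn{\beta} recovered in closed form.
#' With more than two shells a bounded nonlinear least-squares fit over
#' \eqn{(\log\beta, r)} is used.
#'
#' Ratios at or above 1 (no differential attenuation: radius below the
#' resolution floor) are censored to `r = 0`; ratios below the attainable
#' minimum are censored to `r_max`. Both set the resolution-limit flag, as
#' does any fit whose Cramer-Rao standard deviation exceeds half the
#' estimate (when `sigma` is supplied).
#'
#' @param series Tibble with columns `b` and `sbar` (optionally `n_dirs`),
#'   one row per shell; only rows with `b >= b_min` are used.
#' @param protocol Pulse tibble ([pulse_params()]) matched to `series` rows
#'   by b-value.
#' @param D0 Axoplasmic diffusivity, um^2/ms.
#' @param r_max Upper bound of the radius search, um.
#' @param b_min Smallest b-value trusted to be free of extra-cellular
#'   signal (default 6 ms/um^2).
#' @param sigma Optional per-direction noise level; enables the CRLB-based
#'   precision columns and resolution-limit criterion.
#' @return Object of class `radius_fit`: a list with `beta`, `r`,
#'   `residual_norm`, `converged`, `at_resolution_limit`, `crlb_sd_beta`,
#'   `crlb_sd_r`, `n_shells`, plus the inputs used. Use [generics::tidy()]
#'   on it for a tabular view.
#' @export
#' @examples
#' prot <- dplyr::filter(make_connectom_protocol(), b >= 6)
#' sb <- spherical_mean_signal(1, 3, prot)
#' fit <- fit_radius(tibble::tibble(b = prot$b, sbar = sb), prot)
#' fit$r
fit_radius <- function(series, protocol, D0 = mraxon_constants()$D0,
                       r_max = 10, b_min = 6, sigma = NULL) {
  keep <- series$b >= b_min * 0.999
  series <- series[keep, , drop = FALSE]
  series <- series[order(series$b), , drop = FALSE]
  if (nrow(series) < 2) {
    stop("need at least two shells with b >= b_min", call. = FALSE)
  }
  if (any(!is.finite(series$sbar)) || any(series$sbar <= 0)) {
    stop("spherical means must be positive and finite", call. = FALSE)
  }
  prot <- protocol[match(round(series$b, 6), round(protocol$b, 6)), , drop = FALSE]
  if (any(is.na(prot$b))) {
    # tolerate small b mismatches by nearest-shell matching
    prot <- protocol[vapply(series$b, function(bb)
      which.min(abs(protocol$b - bb)), integer(1)), , drop = FALSE]
  }
  y <- series$sbar * sqrt(series$b)
  flag <- FALSE
  converged <- TRUE
  if (nrow(series) == 2) {
    ratio <- y[2] / y[1]
    g <- function(r) {
      ln2 <- ln_attenuation_perp(r, prot[2, ], D0 = D0)
      ln1 <- ln_attenuation_perp(r, prot[1, ], D0 = D0)
      (ln2 - ln1) - log(ratio)
    }
    if (ratio >= 1 - 1e-12) { # float-tolerant: no differential attenuation
      r_hat <- 0
      flag <- TRUE
    } else if (g(r_max) > 0) { # even r_max cannot attenuate this much
      r_hat <- r_max
      flag <- TRUE
    } else {
      r_hat <- uniroot(g, c(0, r_max), tol = 1e-10)$root
    }
    atten <- exp(ln_attenuation_perp(r_hat, prot, D0 = D0))
    beta_hat <- exp(mean(log(y / atten)))
  } else {
    obj <- function(par) {
      mu <- exp(par[1]) * exp(ln_attenuation_perp(par[2], prot, D0 = D0))
      sum((y - mu)^2)
    }
    init <- c(log(y[1]), 1)
    fit <- optim(init, obj, method = "L-BFGS-B",
                 lower = c(-20, 0), upper = c(20, r_max),
                 control = list(factr = 1e4))
    converged <- fit$convergence == 0
    beta_hat <- exp(fit$par[1])
    r_hat <- fit$par[2]
    if (r_hat <= 1e-8 || r_hat >= r_max - 1e-8) flag <- TRUE
  }
  mu <- beta_hat * exp(ln_attenuation_perp(r_hat, prot, D0 = D0))
  res_norm <- sqrt(sum((y - mu)^2))
  sd_beta <- sd_r <- NA_real_
  if (!is.null(sigma) && r_hat > 0) {
    n_dirs <- if ("n_dirs" %in% names(series)) series$n_dirs else
      if ("n_dirs" %in% names(prot)) prot$n_dirs else rep(1, nrow(prot))
    cv <- crlb(prot, beta = beta_hat, r = r_hat, D0 = D0,
               sigma = sigma, n_dirs = n_dirs)
    sd_beta <- sqrt(cv[1, 1])
    sd_r <- sqrt(cv[2, 2])
    if (is.finite(sd_r) && sd_r > r_hat / 2) flag <- TRUE
  }
  structure(list(beta = beta_hat, r = r_hat, residual_norm = res_norm,
                 converged = converged, at_resolution_limit = flag,
                 crlb_sd_beta = sd_beta, crlb_sd_r = sd_r,
                 n_shells = nrow(series), series = series, D0 = D0,
                 r_max = r_max),
            class = "radius_fit")
}

#' @export
print.radius_fit <- function(x, ...) {
  cat(sprintf("<radius_fit> r = %.4f um, beta = %.4f (%d shells)%s\n",
              x$r, x$beta, x$n_shells,
              if (x$at_resolution_limit) " [resolution limit]" else ""))
  invisible(x)
}

#' Cramer-Rao lower bound for the two-parameter radius fit
#'
#' Fisher information for \eqn{(\beta, r)} under independent Gaussian noise
#' on per-shell spherical means with variance \eqn{\sigma^2/n_{\rm dirs}}.
#' The model derivative in `r` uses the analytic derivative of the
#' Gaussian-phase log-attenuation.
#'
#' @param protocol Pulse tibble, one row per shell (b > 0).
#' @param beta,r Model parameters at which the bound is evaluated (r > 0).
#' @param D0 Axoplasmic diffusivity.
#' @param sigma Per-direction noise level (scalar or one value per shell).
#' @param n_dirs Directions per shell (recycled).
#' @return 2 x 2 covariance lower bound, rows/cols (beta, r).
#' @export
crlb <- function(protocol, beta, r, D0 = mraxon_constants()$D0,
                 sigma, n_dirs = protocol$n_dirs) {
  if (r <= 0) stop("CRLB diverges at r = 0; supply r > 0", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  sigma <- rep_len(sigma, nrow(protocol))
  if (is.null(n_dirs)) stop("direction counts required", call. = FALSE)
  n_dirs <- rep_len(n_dirs, nrow(protocol))
  lnS <- ln_attenuation_perp(r, protocol, D0 = D0)
  mu <- beta / sqrt(protocol$b) * exp(lnS)
  dmu_dbeta <- mu / beta
  dmu_dr <- mu * ln_attenuation_perp_dr(r, protocol, D0 = D0)
  J <- cbind(dmu_dbeta, dmu_dr)
  w <- n_dirs / sigma^2
  info <- crossprod(J, w * J)
  if (rcond(info) < 1e-14) {
    stop("singular Fisher information: parameters unidentifiable with this protocol",
         call. = FALSE)
  }
  solve(info)
}

#' Cramer-Rao landscape over pulse timings
#'
#' Evaluates the achievable radius precision over a grid of pulse durations
#' and separations for a two-shell (b = 6, 30 ms/um^2) protocol under a
#' maximum-gradient constraint and an echo-time budget
#' (`delta + Delta <= te_budget`). Cells with `delta > Delta`, gradient
#' demand above `G_max`, or timing above budget are flagged invalid rather
#' than errored.
#'
#' @param delta_grid,Delta_grid Grids of pulse duration/separation (ms).
#' @param G_max Gradient ceiling, mT/m.
#' @param te_budget Echo-time budget constraint on `delta + Delta`, ms.
#' @param b_shells The two shell b-values, ms/um^2.
#' @param n_dirs Directions per shell.
#' @param beta,r,D0,sigma Model/noise parameters for the bound.
#' @return Tibble with `delta`, `Delta`, `valid`, `G_high` (gradient needed
#'   for the top shell) and `sd_r` (CRLB standard deviation of the radius,
#'   um; NA where invalid).
#' @export
protocol_landscape <- function(delta_grid, Delta_grid, G_max = 273,
                               te_budget = 66, b_shells = c(6, 30),
                               n_dirs = c(120, 240), beta = 0.62, r = 2,
                               D0 = mraxon_constants()$D0, sigma = 1 / 30) {
  grid <- tidyr::expand_grid(delta = delta_grid, Delta = Delta_grid)
  res <- purrr::pmap_dfr(grid, function(delta, Delta) {
    if (delta > Delta || delta + Delta > te_budget) {
      return(tibble::tibble(delta = delta, Delta = Delta, valid = FALSE,
                            G_high = NA_real_, sd_r = NA_real_))
    }
    prot <- pulse_params(b = b_shells, delta = delta, Delta = Delta,
                         n_dirs = n_dirs)
    if (max(prot$G) > G_max) {
      return(tibble::tibble(delta = delta, Delta = Delta, valid = FALSE,
                            G_high = max(prot$G), sd_r = NA_real_))
    }
    cv <- crlb(prot, beta = beta, r = r, D0 = D0, sigma = sigma,
               n_dirs = n_dirs)
    tibble::tibble(delta = delta, Delta = Delta, valid = TRUE,
                   G_high = max(prot$G), sd_r = sqrt(cv[2, 2]))
  })
  res
}

#' Direction allocation across candidate shells: uniform-in-G vs optimised
#'
#' Builds a candidate shell ladder by uniform sampling of the gradient
#' amplitude up to `G_max` (at fixed pulse timings) and compares two ways
#' of spending a total direction budget: spread uniformly over the ladder,
#' or allocated to minimise the Cramer-Rao bound on the radius (solved by
#' greedy exchange over integer direction counts). The optimised design
#' concentrates the budget on the extreme b-values.
#'
#' @param n_candidates Number of candidate shells (uniform in G).
#' @param total_dirs Total direction budget.
#' @param delta,Delta Pulse timings, ms.
#' @param G_max Maximum gradient, mT/m.
#' @param b_min Smallest usable b-value (extra-cellular suppression).
#' @param beta,r,D0,sigma Model/noise parameters.
#' @return Tibble with `b`, `G`, `w_uniform`, `w_optimized` (direction
#'   fractions) plus attributes `sd_r_uniform`, `sd_r_optimized`.
#' @export
optimize_shell_placement <- function(n_candidates = 12, total_dirs = 360,
                                     delta = 15, Delta = 30, G_max = 273,
                                     b_min = 6, beta = 0.62, r = 2,
                                     D0 = mraxon_constants()$D0,
                                     sigma = 1 / 30) {
  G <- seq(0, G_max, length.out = n_candidates + 1)[-1]
  prot <- pulse_params(G = G, delta = delta, Delta = Delta)
  prot <- dplyr::filter(prot, .data$b >= b_min)
  m <- nrow(prot)
  sd_for <- function(counts) {
    use <- counts > 0
    if (sum(use) < 2) return(Inf)
    cv <- try(crlb(prot[use, ], beta = beta, r = r, D0 = D0, sigma = sigma,
                   n_dirs = counts[use]), silent = TRUE)
    if (inherits(cv, "try-error")) Inf else sqrt(cv[2, 2])
  }
  uniform <- rep(floor(total_dirs / m), m)
  uniform[seq_len(total_dirs - sum(uniform))] <-
    uniform[seq_len(total_dirs - sum(uniform))] + 1
  # greedy exchange from the uniform start
  counts <- uniform
  best <- sd_for(counts)
  repeat {
    improved <- FALSE
    for (from in seq_len(m)) {
      if (counts[from] == 0) next
      for (to in seq_len(m)) {
        if (to == from) next
        cand <- counts
        step <- min(cand[from], max(1, floor(total_dirs / (4 * m))))
        cand[from] <- cand[from] - step
        cand[to] <- cand[to] + step
        s <- sd_for(cand)
        if (s < best * (1 - 1e-9)) {
          counts <- cand
          best <- s
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  out <- tibble::tibble(b = prot$b, G = prot$G,
                        w_uniform = uniform / total_dirs,
                        w_optimized = counts / total_dirs)
  attr(out, "sd_r_uniform") <- sd_for(uniform)
  attr(out, "sd_r_optimized") <- best
  out
}
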