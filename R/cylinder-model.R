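#' Roots of the derivative of the Bessel function J1
#'
#' The Gaussian-phase expression for diffusion restricted in a cylinder sums
#' over the ordered roots \eqn{\alpha_m} of \eqn{dJ_1(\alpha)/d\alpha = 0}.
#' Roots are located by sign changes of \eqn{J_1'(x) = (J_0(x) - J_2(x))/2}
#' on a fine grid, polished with [stats::uniroot()], and cached for the
#' session.
#'
#' @param m Number of roots required.
#' @return Numeric vector of the first `m` roots, strictly increasing
#'   (first root 1.8412...).
#' @export
bessel_prime_roots <- function(m = 200) {
  stopifnot(m >= 1)
  cached <- .mraxon_cache$bessel_roots
  if (!is.null(cached) && length(cached) >= m) {
    return(cached[seq_len(m)])
  }
  f <- function(x) (besselJ(x, 0) - besselJ(x, 2)) / 2
  # roots are ~pi apart; grid step 0.2 cannot skip a sign change
  upper <- (m + 2) * pi + 2
  x <- seq(1, upper, by = 0.2)
  fx <- f(x)
  idx <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(f, c(x[i], x[i + 1]), tol = 1e-13)$root
  }, numeric(1))
  if (length(roots) < m) {
    stop("failed to bracket the requested number of Bessel roots", call. = FALSE)
  }
  roots <- roots[seq_len(max(m, length(roots)))]
  .mraxon_cache$bessel_roots <- roots
  roots[seq_len(m)]
}

# Per-root contribution to the cylinder sum and its derivative w.r.t. t_c.
# Written so that the t_c -> 0 limit is finite (no 1/t_c overflow):
#   term_m = 2*delta/(a^4 (a^2-1)) + t_c * E(t_c) / (a^6 (a^2-1))
# with E collecting the exponential transients.
.cyl_terms <- function(roots, tc, delta, Delta, deriv = FALSE) {
  a2 <- roots^2
  k4 <- a2^2 * (a2 - 1)
  k6 <- a2^3 * (a2 - 1)
  if (tc <= 0) {
    out <- 2 * delta / k4
    if (deriv) attr(out, "dtc") <- rep(0, length(roots))
    return(out)
  }
  e1 <- exp(-a2 * delta / tc)
  e2 <- exp(-a2 * Delta / tc)
  e3 <- exp(-a2 * (Delta - delta) / tc)
  e4 <- exp(-a2 * (Delta + delta) / tc)
  E <- -2 + 2 * e1 + 2 * e2 - e3 - e4
  out <- 2 * delta / k4 + tc * E / k6
  if (deriv) {
    # d/dtc [tc * E] = E + (a2/tc) * (2*delta*e1 + 2*Delta*e2
    #                                 - (Delta-delta)*e3 - (Delta+delta)*e4)
    tcEp <- (a2 / tc) * (2 * delta * e1 + 2 * Delta * e2 -
                           (Delta - delta) * e3 - (Delta + delta) * e4)
    attr(out, "dtc") <- (E + tcEp) / k6
  }
  out
}

#' Log-attenuation of the restricted perpendicular cylinder signal
#'
#' Gaussian-phase approximation for the diffusion-weighted signal of spins
#' confined to an impermeable cylinder of radius `r`, with the gradient
#' perpendicular to the cylinder axis:
#' \deqn{\ln S_\perp = -\frac{2 q^2 r^4}{D_0} \sum_m
#'   \frac{t_c}{\alpha_m^6(\alpha_m^2-1)}\Big[
#'   2\alpha_m^2\delta/t_c - 2 + 2e^{-\alpha_m^2\delta/t_c}
#'   + 2e^{-\alpha_m^2\Delta/t_c} - e^{-\alpha_m^2(\Delta-\delta)/t_c}
#'   - e^{-\alpha_m^2(\Delta+\delta)/t_c}\Big],}
#' where \eqn{t_c = r^2/D_0} is the diffusion time across the cylinder and
#' \eqn{\alpha_m} are the roots of \eqn{J_1'}. The series is truncated
#' adaptively: summation stops once the next term changes the partial sum
#' by less than `tol` (relative).
#'
#' In the wide-pulse regime (\eqn{\delta \gg t_c}) this reduces to the
#' Neuman limit \eqn{\ln S_\perp \approx -c\, q^2 r^4 \delta / D_0} with
#' \eqn{c = 4\sum_m [\alpha_m^4(\alpha_m^2-1)]^{-1} = 7/48}.
#'
#' @param r Cylinder radius (um); vectorised, recycled against the pulse.
#' @param pulse Pulse tibble from [pulse_params()] (columns `q`, `delta`,
#'   `Delta`), or one row per element of `r`.
#' @param D0 Axoplasmic diffusivity, um^2/ms.
#' @param tol Relative truncation tolerance for the root sum.
#' @param m_max Maximum number of roots before a truncation error is raised.
#' @return Non-positive log-attenuation values, one per (r, pulse) pair.
#' @export
#' @examples
#' p <- pulse_params(G = 273, delta = 15, Delta = 30)
#' ln_attenuation_perp(1, p)
ln_attenuation_perp <- function(r, pulse, D0 = mraxon_constants()$D0,
                                tol = mraxon_constants()$root_tol,
                                m_max = mraxon_constants()$max_roots) {
  if (any(r < 0)) stop("radius must be non-negative", call. = FALSE)
  if (D0 <= 0) stop("D0 must be positive", call. = FALSE)
  n <- max(length(r), nrow(pulse))
  r <- rep_len(r, n)
  q <- rep_len(pulse$q, n)
  delta <- rep_len(pulse$delta, n)
  Delta <- rep_len(pulse$Delta, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (r[i] == 0 || q[i] == 0) next
    tc <- r[i]^2 / D0
    m <- 32L
    repeat {
      roots <- bessel_prime_roots(m)
      terms <- .cyl_terms(roots, tc, delta[i], Delta[i])
      s <- cumsum(terms)
      total <- s[m]
      if (terms[m] < tol * total) {
        # earliest index already meeting the next-term criterion
        k <- which(terms < tol * s)[1]
        total <- s[max(k, 1L)]
        break
      }
      if (m >= m_max) {
        stop("cylinder root sum did not converge within m_max roots",
             call. = FALSE)
      }
      m <- min(2L * m, m_max)
    }
    out[i] <- -(2 * q[i]^2 * r[i]^4 / D0) * total
  }
  out
}

#' Derivative of the cylinder log-attenuation with respect to radius
#'
#' Analytic derivative of [ln_attenuation_perp()] in `r`, used for
#' Fisher-information (Cramer-Rao) computations. Differentiates both the
#' explicit \eqn{r^4} prefactor and the dependence through
#' \eqn{t_c = r^2/D_0}.
#'
#' @inheritParams ln_attenuation_perp
#' @return d ln S_perp / d r, per (r, pulse) pair.
#' @export
ln_attenuation_perp_dr <- function(r, pulse, D0 = mraxon_constants()$D0,
                                   m_max = mraxon_constants()$max_roots) {
  n <- max(length(r), nrow(pulse))
  r <- rep_len(r, n)
  q <- rep_len(pulse$q, n)
  delta <- rep_len(pulse$delta, n)
  Delta <- rep_len(pulse$Delta, n)
  out <- numeric(n)
  roots <- bessel_prime_roots(64L)
  for (i in seq_len(n)) {
    if (r[i] == 0 || q[i] == 0) next
    tc <- r[i]^2 / D0
    terms <- .cyl_terms(roots, tc, delta[i], Delta[i], deriv = TRUE)
    dtc <- attr(terms, "dtc")
    Fsum <- sum(terms)
    dF <- 4 * r[i]^3 * Fsum + r[i]^4 * sum(dtc) * (2 * r[i] / D0)
    out[i] <- -(2 * q[i]^2 / D0) * dF
  }
  out
}

#' Spherically averaged intra-axonal signal
#'
#' High-b powder average of a thin cylinder population:
#' \deqn{\bar S(b) = \beta\, b^{-1/2} S_\perp(r; q, \delta, \Delta),}
#' where the \eqn{1/\sqrt b} factor is the wide-b spherical mean of a
#' zero-radius fiber (stick) and \eqn{\beta} is a nuisance amplitude
#' absorbing the intra-axonal signal fraction and parallel diffusivity
#' (for a stick fraction f, \eqn{\beta = f\sqrt{\pi/4}/\sqrt{D_{a\parallel}}}).
#' Valid only at strong diffusion weighting where the extra-cellular signal
#' is suppressed.
#'
#' @param beta Positive nuisance amplitude, signal (ms/um^2)^(1/2).
#' @inheritParams ln_attenuation_perp
#' @return Spherical-mean signal value(s), > 0.
#' @export
#' @examples
#' p <- pulse_params(G = 273, delta = 15, Delta = 30)
#' spherical_mean_signal(1, 2, p)
spherical_mean_signal <- function(beta, r, pulse,
                                  D0 = mraxon_constants()$D0, ...) {
  if (any(beta <= 0)) stop("beta must be positive", call. = FALSE)
  if (any(pulse$b <= 0)) {
    stop("spherical-mean model requires b > 0 (suppressed extra-cellular regime)",
         call. = FALSE)
  }
  lnS <- ln_attenuation_perp(r, pulse, D0 = D0, ...)
  n <- length(lnS)
  rep_len(beta, n) / sqrt(rep_len(pulse$b, n)) * exp(lnS)
}
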