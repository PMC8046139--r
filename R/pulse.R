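#' Stejskal-Tanner pulse parameters
#'
#' Builds a tibble of pulsed-gradient spin-echo parameters, one row per
#' shell. Either the gradient amplitude `G` or the b-value `b` must be
#' supplied; the other is derived through
#' \deqn{b = q^2 \delta^2 (\Delta - \delta/3), \qquad q = \gamma G,}
#' with \eqn{\gamma} the proton gyromagnetic ratio in package units
#' (rad ms^-1 um^-1 per mT/m), so b is in ms/um^2.
#'
#' @param G Gradient amplitude(s), mT/m. Recycled against `delta`/`Delta`.
#' @param delta Gradient pulse duration(s), ms.
#' @param Delta Gradient pulse separation(s), ms. Must satisfy
#'   `0 < delta <= Delta`.
#' @param b Optional b-value(s), ms/um^2; used to derive `G` when `G` is
#'   `NULL`. When both are given, consistency is checked to a relative
#'   tolerance of 1e-3.
#' @param n_dirs Optional number of gradient directions per shell (used by
#'   precision calculations).
#'
#' @return A tibble with columns `G`, `delta`, `Delta`, `q`, `b` and
#'   (if given) `n_dirs`.
#' @export
#' @examples
#' pulse_params(G = 273, delta = 15, Delta = 30) # b ~ 30 ms/um^2
pulse_params <- function(G = NULL, delta, Delta, b = NULL, n_dirs = NULL) {
  gam <- mraxon_constants()$gyromagnetic_ratio
  if (is.null(G) && is.null(b)) {
    stop("supply at least one of `G` or `b`", call. = FALSE)
  }
  n <- max(length(G), length(b), length(delta), length(Delta))
  delta <- rep_len(delta, n)
  Delta <- rep_len(Delta, n)
  if (any(delta <= 0) || any(delta > Delta)) {
    stop("pulse parameters require 0 < delta <= Delta", call. = FALSE)
  }
  tau <- delta^2 * (Delta - delta / 3)
  if (is.null(G)) {
    b <- rep_len(b, n)
    if (any(b < 0)) stop("b must be non-negative", call. = FALSE)
    q <- sqrt(b / tau)
    G <- q / gam
  } else {
    G <- rep_len(G, n)
    if (any(G < 0)) stop("G must be non-negative", call. = FALSE)
    q <- gam * G
    b_derived <- q^2 * tau
    if (!is.null(b)) {
      b <- rep_len(b, n)
      bad <- abs(b_derived - b) > 1e-3 * pmax(b, .Machine$double.eps)
      if (any(bad)) {
        stop("stored b inconsistent with (G, delta, Delta) beyond 1e-3 relative",
             call. = FALSE)
      }
    }
    b <- b_derived
  }
  out <- tibble::tibble(G = G, delta = delta, Delta = Delta, q = q, b = b)
  if (!is.null(n_dirs)) out$n_dirs <- rep_len(n_dirs, n)
  out
}

#' Rescale b-values for gradient nonlinearity
#'
#' Applies a scalar multiplicative correction to the diffusion weighting of a
#' protocol, as done when compensating spatially varying gradient amplitudes
#' with a per-voxel scaling of b. The scale acts on `b` (and hence on `q^2`
#' and `G^2`), leaving the pulse timings untouched; directional variability
#' of the nonlinearity is deliberately not modeled.
#'
#' @param protocol A tibble as returned by [pulse_params()].
#' @param scale Positive multiplicative factor applied to `b`.
#' @return The rescaled protocol tibble.
#' @export
rescale_bvalues <- function(protocol, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  protocol$b <- protocol$b * scale
  protocol$q <- protocol$q * sqrt(scale)
  protocol$G <- protocol$G * sqrt(scale)
  protocol
}
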