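#' Real even-order spherical-harmonic design matrix
#'
#' Real spherical-harmonic basis evaluated at unit direction vectors, even
#' orders only (diffusion signals are antipodally symmetric). Associated
#' Legendre functions come from [pracma::legendre()] (MATLAB convention,
#' Condon-Shortley phase included); normalisation is orthonormal on the
#' sphere, so the spherical mean of the expansion equals
#' `c[1] / sqrt(4*pi)`.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param l_max Maximum even order (0, 2, 4 or 6).
#' @return n x n_coef design matrix.
#' @keywords internal
sh_basis <- function(dirs, l_max = 6) {
  stopifnot(is.matrix(dirs), ncol(dirs) == 3, l_max %% 2 == 0, l_max <= 6)
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("direction vectors must be unit norm (tolerance 1e-6)", call. = FALSE)
  }
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  cols <- list()
  for (l in seq(0, l_max, by = 2)) {
    P <- pracma::legendre(l, ct) # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    k0 <- sqrt((2 * l + 1) / (4 * pi))
    cols[[length(cols) + 1]] <- k0 * P[1, ]
    for (m in seq_len(l)) {
      nlm <- k0 * exp(0.5 * (lgamma(l - m + 1) - lgamma(l + m + 1)))
      cols[[length(cols) + 1]] <- sqrt(2) * nlm * P[m + 1, ] * cos(m * phi)
      cols[[length(cols) + 1]] <- sqrt(2) * nlm * P[m + 1, ] * sin(m * phi)
    }
  }
  do.call(cbind, cols)
}

#' Arithmetic spherical mean of directional signals
#'
#' Baseline estimator: the plain average of the magnitude signals over
#' directions. Biased upwards at low SNR by the Rician noise floor; serves
#' as initialisation and reference for [spherical_mean_ml()].
#'
#' @param signals Vector of magnitude signals.
#' @return The arithmetic mean.
#' @export
naive_spherical_mean <- function(signals) {
  stopifnot(length(signals) >= 1)
  mean(signals)
}

#' Rician maximum-likelihood spherical mean
#'
#' Estimates the spherical mean of a shell as the order-zero coefficient of
#' an even spherical-harmonic expansion (up to `l_max`) fitted by maximum
#' likelihood under Rician-distributed magnitudes with known noise level
#' `sigma`. The fit starts from the least-squares solution and maximises
#' \deqn{\sum_i \log m_i - 2\log\sigma - (m_i^2+\nu_i^2)/(2\sigma^2)
#'       + \log I_0(m_i \nu_i / \sigma^2)}
#' over the harmonic coefficients by BFGS with analytic gradient
#' (convergence tolerance 1e-8 on the objective). When the direction count
#' cannot support the requested order, the order falls back to 2 with a
#' warning.
#'
#' @param signals Vector of non-negative magnitude signals (length n).
#' @param dirs n x 3 matrix of unit gradient directions.
#' @param sigma Rician noise level (signal units, > 0).
#' @param l_max Maximum even harmonic order (default 6; needs n >= 28).
#' @param b Optional b-value carried through to the output.
#' @return One-row tibble with columns `b`, `sbar` (mean over the sphere),
#'   `se` (Gaussian-limit standard error, sigma/sqrt(n)), `n_dirs`,
#'   `l_max_used`, `converged`, `source`.
#' @export
spherical_mean_ml <- function(signals, dirs, sigma, l_max = 6, b = NA_real_) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (any(signals < 0)) stop("magnitude signals must be >= 0", call. = FALSE)
  n <- length(signals)
  n_even_coef <- c(`0` = 1, `2` = 6, `4` = 15, `6` = 28)
  while (l_max > 0 && n < n_even_coef[[as.character(l_max)]]) {
    warning(sprintf("only %d directions: falling back from l_max = %d to %d",
                    n, l_max, l_max - 2), call. = FALSE)
    l_max <- l_max - 2
  }
  X <- sh_basis(dirs, l_max)
  # direction sets can be rank-deficient for the order their count nominally
  # supports; drop the order until the design has full column rank
  while (l_max > 0 && qr(X)$rank < ncol(X)) {
    warning(sprintf("rank-deficient direction set: falling back from l_max = %d to %d",
                    l_max, l_max - 2), call. = FALSE)
    l_max <- l_max - 2
    X <- sh_basis(dirs, l_max)
  }
  c_init <- qr.solve(X, signals)
  nll <- function(cc) {
    nu <- drop(X %*% cc)
    x <- abs(signals * nu) / sigma^2
    l0 <- log(besselI(x, 0, expon.scaled = TRUE)) + x
    -sum(-(signals^2 + nu^2) / (2 * sigma^2) + l0)
  }
  grad <- function(cc) {
    nu <- drop(X %*% cc)
    x <- signals * nu / sigma^2
    ax <- abs(x)
    ratio <- besselI(ax, 1, expon.scaled = TRUE) /
      besselI(ax, 0, expon.scaled = TRUE) * sign(x)
    dnu <- -(-nu / sigma^2 + signals / sigma^2 * ratio)
    drop(crossprod(X, dnu))
  }
  fit <- tryCatch(
    optim(c_init, nll, grad, method = "BFGS",
          control = list(reltol = 1e-8, maxit = 500)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$convergence == 0
  cc <- if (converged) fit$par else c_init
  sbar <- max(cc[1] / sqrt(4 * pi), 0)
  tibble::tibble(b = b, sbar = sbar, se = sigma / sqrt(n), n_dirs = n,
                 l_max_used = l_max, converged = converged, source = "voxel")
}

#' Group b-values into shells
#'
#' Assigns shell indices to b-values, treating values within 5% relative
#' spread (configurable) as one shell.
#'
#' @param bvals Numeric vector of b-values.
#' @param tol Relative grouping tolerance.
#' @return Integer vector of shell ids (0 reserved for b = 0).
#' @export
group_shells <- function(bvals, tol = 0.05) {
  ord <- order(bvals)
  b <- bvals[ord]
  id <- integer(length(b))
  cur <- 0L
  ref <- -Inf
  for (i in seq_along(b)) {
    if (b[i] > ref * (1 + tol)) {
      cur <- cur + 1L
      ref <- b[i]
    }
    id[i] <- cur
  }
  out <- integer(length(bvals))
  out[ord] <- id
  # put b ~ 0 in shell 0
  out[bvals < 0.05 * max(bvals)] <- 0L
  out
}

# 15 distinct elements of a fully symmetric rank-4 tensor, with
# multiplicities, as (i,j,k,l) index rows
.kurtosis_index <- function() {
  idx <- rbind(
    c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
    c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2), c(2, 2, 2, 3),
    c(1, 3, 3, 3), c(2, 3, 3, 3),
    c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
    c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
  )
  mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
  list(idx = idx, mult = mult)
}

.w_direction <- function(w15, n) {
  ki <- .kurtosis_index()
  vapply(seq_len(nrow(ki$idx)), function(r) {
    prod(n[ki$idx[r, ]])
  }, numeric(1)) |>
    (\(p) sum(ki$mult * w15 * p))()
}

#' Diffusion kurtosis fit by weighted linear least squares
#'
#' Fits \eqn{\ln S = \ln S_0 - b D(\hat n) + (b^2/6)\bar D^2 W(\hat n)} to
#' the low-b portion of a multi-shell acquisition (only shells with
#' b <= `b_max` plus b = 0 are consumed; stronger shells are ignored by
#' contract). A two-pass weighted linear least-squares scheme is used:
#' ordinary LS first, then weights equal to the squared predicted signals.
#'
#' @param signals Vector of signals (one voxel, all volumes).
#' @param bvals b-values per volume (ms/um^2).
#' @param dirs n x 3 unit directions (rows for b = 0 volumes are ignored).
#' @param b_max Largest b-value consumed (default 2.5 ms/um^2).
#' @return One-row tibble of DKI metrics: `fa`, `md`, `ad`, `rd`
#'   (um^2/ms), `mk`, `ak`, `rk` (dimensionless), `s0`.
#' @export
fit_dki <- function(signals, bvals, dirs, b_max = 2.5) {
  keep <- bvals <= b_max * 1.0001
  signals <- signals[keep]
  bvals <- bvals[keep]
  dirs <- dirs[keep, , drop = FALSE]
  dwi <- bvals > 0
  if (length(unique(round(bvals[dwi], 6))) < 2 || sum(dwi) < 22) {
    stop("DKI needs >= 2 nonzero shells and >= 22 directions at b <= b_max",
         call. = FALSE)
  }
  ki <- .kurtosis_index()
  n <- nrow(dirs)
  Xd <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
              2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
              2 * dirs[, 2] * dirs[, 3])
  Xw <- sapply(seq_len(15), function(r) {
    ki$mult[r] * dirs[, ki$idx[r, 1]] * dirs[, ki$idx[r, 2]] *
      dirs[, ki$idx[r, 3]] * dirs[, ki$idx[r, 4]]
  })
  X <- cbind(1, -bvals * Xd, (bvals^2 / 6) * Xw)
  y <- log(pmax(signals, .Machine$double.eps))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular DKI design", call. = FALSE)
  theta <- qr.coef(qrX, y)
  for (pass in 1:2) { # two-pass WLLS
    w <- exp(2 * drop(X %*% theta))
    theta <- solve(crossprod(X, w * X), crossprod(X, w * y))
  }
  theta <- drop(theta)
  D <- matrix(c(theta[2], theta[5], theta[6],
                theta[5], theta[3], theta[7],
                theta[6], theta[7], theta[4]), 3, 3)
  eig <- eigen(D, symmetric = TRUE)
  ev <- sort(eig$values, decreasing = TRUE)
  md <- mean(ev)
  fa <- sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  if (!is.finite(fa)) fa <- 0
  w15 <- theta[8:22] / max(md^2, .Machine$double.eps) # fitted md^2 * W
  kdir <- function(nvec) {
    dn <- drop(crossprod(nvec, D %*% nvec))
    md^2 / max(dn, 1e-12)^2 * .w_direction(w15, nvec)
  }
  mk_dirs <- fibonacci_directions(256)
  mk <- mean(apply(mk_dirs, 1, kdir))
  e1 <- eig$vectors[, which.max(eig$values)]
  ak <- kdir(e1)
  e2 <- eig$vectors[, order(eig$values)[2]]
  e3 <- eig$vectors[, which.min(eig$values)]
  ang <- seq(0, pi, length.out = 33)[-33]
  rk <- mean(vapply(ang, function(a) kdir(cos(a) * e2 + sin(a) * e3),
                    numeric(1)))
  tibble::tibble(fa = min(max(fa, 0), 1), md = md, ad = ev[1],
                 rd = mean(ev[2:3]), mk = mk, ak = ak, rk = rk,
                 s0 = exp(theta[1]))
}
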