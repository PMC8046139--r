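#' Deterministic quasi-uniform unit vectors (Fibonacci sphere)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Isotropically distributed gradient directions
#'
#' Electrostatic-repulsion direction sets: points initialised on a Fibonacci
#' sphere and relaxed by minimising the antipodally symmetric Coulomb energy
#' \eqn{\sum_{i<j} 1/\|x_i-x_j\|^2 + 1/\|x_i+x_j\|^2} with projected
#' gradient steps. Deterministic (no RNG) and cached per `n`.
#'
#' @param n Number of directions.
#' @param n_iter Relaxation iterations.
#' @return n x 3 matrix of unit vectors with small mean vector norm.
#' @export
sphere_directions <- function(n, n_iter = 60) {
  key <- sprintf("dirs_%d", n)
  if (!is.null(.mraxon_cache[[key]])) return(.mraxon_cache[[key]])
  x <- fibonacci_directions(n)
  if (n > 2) {
    for (it in seq_len(n_iter)) {
      g <- matrix(0, n, 3)
      for (i in seq_len(n)) {
        d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], `-`)
        d2 <- sweep(x[-i, , drop = FALSE], 2, -x[i, ], `-`)
        r1 <- pmax(rowSums(d1^2), 1e-9)
        r2 <- pmax(rowSums(d2^2), 1e-9)
        # force = -grad of the 1/r^2 pair potential
        g[i, ] <- -2 * colSums(d1 / r1^2) + 2 * colSums(d2 / r2^2)
      }
      # normalise by the largest force and decay the step: bounded
      # displacements keep the relaxation stable
      step <- 0.05 * 0.95^it
      gmax <- max(sqrt(rowSums(g^2)), 1e-12)
      x <- x + step * g / gmax
      x <- x / sqrt(rowSums(x^2))
    }
  }
  .mraxon_cache[[key]] <- x
  x
}

#' Strong-gradient human acquisition protocol
#'
#' Builds the two-session Connectom-style protocol used throughout the
#' package: shells at b = 0.5, 1, 2.5, 6 and 30 ms/um^2 with 30, 30, 30,
#' 120 and 240 isotropically distributed directions, pulse timings
#' delta/Delta = 15/30 ms, plus 23 b = 0 images. Gradient amplitudes are
#' derived from b via the pulse relation; the top shell lands at the
#' hardware ceiling of ~273 mT/m.
#'
#' @param delta,Delta Pulse duration and separation, ms.
#' @return Tibble with one row per shell (`b`, `G`, `q`, `delta`, `Delta`,
#'   `n_dirs`) and a `dirs` list-column of direction matrices (`NULL` for
#'   b = 0).
#' @export
#' @examples
#' make_connectom_protocol()[, c("b", "G", "n_dirs")]
make_connectom_protocol <- function(delta = 15, Delta = 30) {
  b <- c(0, 0.5, 1, 2.5, 6, 30)
  n_dirs <- c(23L, 30L, 30L, 30L, 120L, 240L)
  prot <- pulse_params(b = b, delta = delta, Delta = Delta, n_dirs = n_dirs)
  prot$dirs <- purrr::map2(prot$b, prot$n_dirs,
                           ~ if (.x > 0) sphere_directions(.y) else NULL)
  prot
}

# Volume-weighted (r^2) distribution average of the perpendicular cylinder
# attenuation: <r^2 S_perp(r)> / <r^2>, by quadrature over the radius law.
.dist_perp_attenuation <- function(dist, q_perp, delta, Delta, D0, n_quad = 48) {
  if (dist$family == "point") {
    if (dist$r0 == 0) return(rep(1, length(q_perp)))
    p <- tibble::tibble(q = q_perp, delta = delta, Delta = Delta, b = 1)
    return(exp(ln_attenuation_perp(dist$r0, p, D0 = D0)))
  }
  r_hi <- qgamma(0.9999, shape = dist$shape, scale = dist$scale)
  gl <- pracma::gaussLegendre(n_quad, 0, r_hi)
  wts <- gl$w * dgamma(gl$x, shape = dist$shape, scale = dist$scale) * gl$x^2
  wts <- wts / sum(wts)
  out <- numeric(length(q_perp))
  p <- tibble::tibble(q = 1, delta = delta, Delta = Delta, b = 1)
  # ln S_perp is proportional to q^2: evaluate per radius at unit q, scale
  lnS_unit <- ln_attenuation_perp(gl$x, p[rep(1, n_quad), ], D0 = D0)
  for (i in seq_along(q_perp)) {
    out[i] <- sum(wts * exp(lnS_unit * q_perp[i]^2))
  }
  out
}

#' Tissue parameters for the two-compartment simulator
#'
#' @param f Intra-axonal signal fraction in `[0, 1]`.
#' @param Da_par Intra-axonal parallel diffusivity, um^2/ms.
#' @param De_par,De_perp Extra-cellular parallel/perpendicular
#'   diffusivities, um^2/ms.
#' @param dist Axon radius distribution ([axon_gamma()] / [axon_point()]).
#' @param fibers k x 3 matrix of unit fiber directions.
#' @param weights Fiber weights (normalised internally).
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(f = 0.7, Da_par = 2.0, De_par = 2.0, De_perp = 0.5,
                          dist = axon_point(3), fibers = matrix(c(1, 0, 0), 1),
                          weights = NULL) {
  stopifnot(f >= 0, f <= 1, Da_par > 0, Da_par <= 3.5,
            De_par > 0, De_par <= 3.5, De_perp > 0, De_perp <= 3.5)
  if (is.null(dim(fibers))) fibers <- matrix(fibers, nrow = 1)
  fibers <- fibers / sqrt(rowSums(fibers^2))
  if (is.null(weights)) weights <- rep(1 / nrow(fibers), nrow(fibers))
  weights <- weights / sum(weights)
  structure(list(f = f, Da_par = Da_par, De_par = De_par, De_perp = De_perp,
                 dist = dist, fibers = fibers, weights = weights),
            class = "tissue_params")
}

# Noiseless directional signal of the two-compartment model at unit S0
.voxel_signal <- function(tissue, dirs, b, q, delta, Delta, D0) {
  sig <- numeric(nrow(dirs))
  for (j in seq_len(nrow(tissue$fibers))) {
    v <- tissue$fibers[j, ]
    cpsi <- pmin(pmax(drop(dirs %*% v), -1), 1)
    spsi2 <- pmax(1 - cpsi^2, 0)
    intra <- exp(-b * tissue$Da_par * cpsi^2) *
      .dist_perp_attenuation(tissue$dist, q * sqrt(spsi2), delta, Delta, D0)
    extra <- exp(-b * (tissue$De_perp + (tissue$De_par - tissue$De_perp) * cpsi^2))
    sig <- sig + tissue$weights[j] *
      (tissue$f * intra + (1 - tissue$f) * extra)
  }
  sig
}

#' Simulate directional signals for a single voxel
#'
#' Two-compartment model: intra-axonal restricted cylinders (axial Gaussian
#' decay with `Da_par` times the Gaussian-phase radial attenuation,
#' integrated over the radius distribution with r^2 spin-count weighting)
#' plus an axially symmetric extra-cellular Gaussian tensor, mixed by the
#' signal fraction `f`. Magnitude (Rician) noise is added via two
#' independent Gaussian channels with `sigma = 1/snr` (unit b = 0 signal).
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol Protocol tibble from [make_connectom_protocol()].
#' @param snr Signal-to-noise ratio at b = 0 (Inf for noiseless).
#' @param seed Optional RNG seed (set locally for reproducibility).
#' @param D0 Axoplasmic diffusivity for the restricted compartment.
#' @return List of class `voxel_sim` with elements `data` (tibble: `shell`,
#'   `b`, direction components, `clean`, `signal`), `truth` (tibble of
#'   analytic noiseless spherical means per shell), `sigma`, `beta_true`,
#'   `r_eff_true`.
#' @export
simulate_voxel <- function(tissue, protocol = make_connectom_protocol(),
                           snr = 30, seed = NULL,
                           D0 = mraxon_constants()$D0) {
  stopifnot(inherits(tissue, "tissue_params"), snr > 0)
  if (!is.null(seed)) set.seed(seed)
  shells <- dplyr::filter(protocol, .data$b > 0)
  rows <- purrr::pmap(list(shells$b, shells$q, shells$delta, shells$Delta,
                           shells$dirs, seq_len(nrow(shells))),
    function(b, q, delta, Delta, dirs, k) {
      clean <- .voxel_signal(tissue, dirs, b, q, delta, Delta, D0)
      tibble::tibble(shell = k, b = b, gx = dirs[, 1], gy = dirs[, 2],
                     gz = dirs[, 3], clean = clean)
    })
  data <- dplyr::bind_rows(rows)
  sigma <- 1 / snr
  if (is.finite(snr)) {
    n <- nrow(data)
    data$signal <- sqrt((data$clean + rnorm(n, 0, sigma))^2 +
                          rnorm(n, 0, sigma)^2)
  } else {
    data$signal <- data$clean
  }
  # analytic spherical mean of the noiseless model (axially symmetric
  # kernel: quadrature over cos(psi); identical for all fiber configs)
  gl <- pracma::gaussLegendre(64, 0, 1)
  truth <- purrr::pmap_dfr(
    list(shells$b, shells$q, shells$delta, shells$Delta, seq_len(nrow(shells))),
    function(b, q, delta, Delta, k) {
      intra <- sum(gl$w * exp(-b * tissue$Da_par * gl$x^2) *
        .dist_perp_attenuation(tissue$dist, q * sqrt(1 - gl$x^2),
                               delta, Delta, D0))
      extra <- sum(gl$w * exp(-b * (tissue$De_perp +
        (tissue$De_par - tissue$De_perp) * gl$x^2)))
      tibble::tibble(shell = k, b = b,
                     sbar_intra = tissue$f * intra,
                     sbar_extra = (1 - tissue$f) * extra,
                     sbar = tissue$f * intra + (1 - tissue$f) * extra)
    })
  structure(list(
    data = data, truth = truth, sigma = sigma,
    beta_true = tissue$f * sqrt(pi / 4) / sqrt(tissue$Da_par),
    r_eff_true = effective_radius(tissue$dist)
  ), class = "voxel_sim")
}

#' Simulate a fiber-bundle dataset with an along-tract radius profile
#'
#' Generates a synthetic stand-in for tractography plus scanning: a bundle
#' of streamlines scattered around a parametric centerline, and voxelized
#' spherical-mean maps for the strong shells (b >= 6) consistent with a
#' prescribed effective-radius profile along the arc length. Map noise is
#' Gaussian with per-shell standard deviation `sigma/sqrt(n_dirs)`
#' (direction-averaged magnitude noise in the high-SNR limit).
#'
#' @param centerline m x 3 matrix of centerline points (mm).
#' @param n_streamlines Number of streamlines.
#' @param spread Bundle radius (mm): streamline offsets are uniform in a
#'   disk of this radius perpendicular to the mean tract direction.
#' @param profile Function of normalised arc position s in `[0, 1]`
#'   returning the true effective radius (um).
#' @param beta True nuisance amplitude (constant along the tract).
#' @param protocol Acquisition protocol; only shells with b >= 6 are
#'   voxelized.
#' @param sigma Per-direction noise level (b = 0 signal units).
#' @param voxel_dim Isotropic voxel size, mm.
#' @param seed RNG seed.
#' @param D0 Axoplasmic diffusivity.
#' @return List of class `bundle_dataset`: `bundle`, `shells`, noiseless
#'   array `smean_clean` (x, y, z, shell), noisy `smean`, `origin`,
#'   `voxel_dim`, `sigma`, `profile`, `beta`, `seed`.
#' @export
simulate_bundle_dataset <- function(centerline, n_streamlines = 100,
                                    spread = 6, profile = function(s) 3,
                                    beta = 0.62,
                                    protocol = make_connectom_protocol(),
                                    sigma = 1 / 30, voxel_dim = 2.5,
                                    seed = 1, D0 = mraxon_constants()$D0) {
  stopifnot(is.matrix(centerline), ncol(centerline) == 3, spread > 0)
  set.seed(seed)
  seg <- diff(centerline)
  arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  s_of <- function(pts) { # normalised arc position of nearest centerline point
    d2 <- outer(rowSums(pts^2), rowSums(centerline^2), `+`) -
      2 * pts %*% t(centerline)
    arc[max.col(-d2)] / max(arc)
  }
  axis_dir <- centerline[nrow(centerline), ] - centerline[1, ]
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  e2 <- if (abs(axis_dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- e2 - sum(e2 * axis_dir) * axis_dir
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis_dir[2] * e2[3] - axis_dir[3] * e2[2],
          axis_dir[3] * e2[1] - axis_dir[1] * e2[3],
          axis_dir[1] * e2[2] - axis_dir[2] * e2[1])
  rad <- spread * sqrt(runif(n_streamlines))
  ang <- runif(n_streamlines, 0, 2 * pi)
  streamlines <- lapply(seq_len(n_streamlines), function(i) {
    off <- rad[i] * (cos(ang[i]) * e2 + sin(ang[i]) * e3)
    wig <- 0.2 * sin(2 * pi * arc / max(arc) + ang[i])
    centerline + matrix(off, nrow(centerline), 3, byrow = TRUE) +
      outer(wig, e2)
  })
  bundle <- new_bundle(streamlines, voxel_dim = rep(voxel_dim, 3))
  shells <- dplyr::filter(protocol, .data$b >= 6)
  lo <- apply(do.call(rbind, streamlines), 2, min) - 2 * voxel_dim
  hi <- apply(do.call(rbind, streamlines), 2, max) + 2 * voxel_dim
  dims <- pmax(ceiling((hi - lo) / voxel_dim), 1)
  origin <- lo
  centers <- as.matrix(expand.grid(
    x = origin[1] + (seq_len(dims[1]) - 0.5) * voxel_dim,
    y = origin[2] + (seq_len(dims[2]) - 0.5) * voxel_dim,
    z = origin[3] + (seq_len(dims[3]) - 0.5) * voxel_dim))
  s_pos <- s_of(centers)
  r_true <- profile(s_pos)
  smean_clean <- array(0, c(dims, nrow(shells)))
  for (k in seq_len(nrow(shells))) {
    vals <- spherical_mean_signal(beta, r_true, shells[k, ], D0 = D0)
    smean_clean[, , , k] <- array(vals, dims)
  }
  smean <- smean_clean
  for (k in seq_len(nrow(shells))) {
    smean[, , , k] <- smean_clean[, , , k] +
      array(rnorm(prod(dims), 0, sigma / sqrt(shells$n_dirs[k])), dims)
  }
  structure(list(bundle = bundle, shells = shells,
                 smean_clean = smean_clean, smean = smean,
                 origin = origin, voxel_dim = rep(voxel_dim, 3),
                 sigma = sigma, profile = profile, beta = beta, seed = seed,
                 D0 = D0),
            class = "bundle_dataset")
}

#' Test-retest replicate pair of a synthetic dataset
#'
#' Draws two independent noise realisations over the shared noiseless
#' spherical-mean maps of a [simulate_bundle_dataset()] object, emulating
#' back-to-back scan sessions with identical ground truth.
#'
#' @param dataset A `bundle_dataset`.
#' @param seeds Integer pair of RNG seeds, one per session.
#' @param scale_offset Optional global multiplicative miscalibration applied
#'   to the second session (default 0 = none).
#' @return List with elements `test` and `retest`, each a `bundle_dataset`.
#' @export
simulate_test_retest <- function(dataset, seeds = c(101, 202),
                                 scale_offset = 0) {
  stopifnot(inherits(dataset, "bundle_dataset"), length(seeds) == 2)
  redraw <- function(seed, scale) {
    set.seed(seed)
    out <- dataset
    dims <- dim(dataset$smean_clean)
    for (k in seq_len(dims[4])) {
      out$smean[, , , k] <- (1 + scale) * dataset$smean_clean[, , , k] +
        array(rnorm(prod(dims[1:3]), 0,
                    dataset$sigma / sqrt(dataset$shells$n_dirs[k])), dims[1:3])
    }
    out$seed <- seed
    out
  }
  list(test = redraw(seeds[1], 0), retest = redraw(seeds[2], scale_offset))
}

#' Two-cohort group study simulator
#'
#' Simulates replicate two-group studies in which the group means of a
#' metric differ by `effect_pct` percent and each subject's measurement
#' carries a coefficient of variation `trv_pct / sqrt(2)` (the
#' per-measurement CV implied by a test-retest variability of `trv_pct`
#' under Gaussian repeats). Returns the empirical rejection rate of the
#' two-sided two-sample t-test.
#'
#' @param effect_pct Percentage difference between cohort means.
#' @param trv_pct Test-retest variability, percent.
#' @param n_per_group Subjects per cohort.
#' @param n_replicates Number of simulated studies.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @return List with `rejection_rate`, `n_replicates`, `p_values`.
#' @export
simulate_two_cohorts <- function(effect_pct, trv_pct, n_per_group,
                                 n_replicates = 1000, alpha = 0.05,
                                 seed = 1) {
  stopifnot(effect_pct >= 0, trv_pct > 0, n_per_group >= 2)
  set.seed(seed)
  cv <- trv_pct / 100 / sqrt(2)
  mu1 <- 1
  mu2 <- 1 + effect_pct / 100
  # measurement noise scaled to the reference cohort mean, matching the
  # equal-variance convention of the analytic power computation
  pvals <- vapply(seq_len(n_replicates), function(i) {
    g1 <- mu1 + rnorm(n_per_group, 0, cv * mu1)
    g2 <- mu2 + rnorm(n_per_group, 0, cv * mu1)
    stats::t.test(g1, g2, var.equal = TRUE)$p.value
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), n_replicates = n_replicates,
       p_values = pvals)
}
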