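test_that("the strong-gradient protocol is internally consistent", {
  prot <- make_connectom_protocol()
  expect_equal(prot$b, c(0, 0.5, 1, 2.5, 6, 30), tolerance = 1e-9)
  expect_equal(prot$n_dirs, c(23L, 30L, 30L, 30L, 120L, 240L))
  expect_equal(prot$delta, rep(15, 6))
  expect_equal(prot$Delta, rep(30, 6))
  # printed protocol self-consistency: the top shell needs ~273 mT/m
  expect_equal(max(prot$G), 273, tolerance = 1e-3)
  expect_equal(prot$n_dirs[prot$b == 6], 120L)
  # direction sets: unit norm and antipodal balance
  for (d in prot$dirs[prot$b > 0]) {
    expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-9)
    expect_lt(sqrt(sum(colMeans(d)^2)), 0.05)
  }
})

test_that("a zero-radius single fiber reduces to the stick model exactly", {
  tissue <- tissue_params(f = 1, Da_par = 2, dist = axon_point(0),
                          fibers = c(0, 0, 1))
  vs <- simulate_voxel(tissue, snr = Inf)
  expected <- exp(-vs$data$b * 2 * vs$data$gz^2)
  expect_equal(vs$data$clean, expected, tolerance = 1e-12)
})

test_that("powder averages are invariant to fiber crossing geometry", {
  # identical radial kernel, 1 fiber vs 3-way crossing: dense quadrature
  dirs <- mraxon:::fibonacci_directions(20000)
  prot <- dplyr::filter(make_connectom_protocol(), b >= 6)
  t1 <- tissue_params(f = 1, dist = axon_gamma(5, 0.356), fibers = c(1, 0, 0))
  f3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))
  t3 <- tissue_params(f = 1, dist = axon_gamma(5, 0.356), fibers = f3)
  for (k in 1:2) {
    s1 <- mean(mraxon:::.voxel_signal(t1, dirs, prot$b[k], prot$q[k],
                                      15, 30, 2.5))
    s3 <- mean(mraxon:::.voxel_signal(t3, dirs, prot$b[k], prot$q[k],
                                      15, 30, 2.5))
    expect_lt(abs(s1 - s3) / s1, 1e-4)
  }
})

test_that("the extra-cellular compartment is negligible at b >= 6 but dominant at low b", {
  tissue <- tissue_params(f = 0.6, De_perp = 0.5, dist = axon_gamma(5, 0.356))
  vs <- simulate_voxel(tissue, snr = Inf)
  frac <- vs$truth$sbar_extra / vs$truth$sbar
  expect_lt(frac[vs$truth$b == 6], 0.05)
  expect_lt(frac[vs$truth$b == 30], 1e-4)
  expect_gt(frac[vs$truth$b == 1], 0.2)
})

test_that("voxel simulation is reproducible per seed and Rician-noised", {
  tissue <- tissue_params()
  v1 <- simulate_voxel(tissue, snr = 30, seed = 5)
  v2 <- simulate_voxel(tissue, snr = 30, seed = 5)
  expect_identical(v1$data$signal, v2$data$signal)
  v3 <- simulate_voxel(tissue, snr = 30, seed = 6)
  expect_false(identical(v1$data$signal, v3$data$signal))
  expect_true(all(v1$data$signal >= 0))
  expect_equal(v1$sigma, 1 / 30)
})

test_that("noiseless simulate_voxel output closes the loop with fit_radius", {
  # fully suppressed extra-cellular regime: the estimator must invert the
  # generator's forward model to within 2% across the sensitive range
  prot <- strong_shells()
  for (r0 in c(2, 3, 5)) {
    tissue <- tissue_params(f = 1, dist = axon_point(r0))
    vs <- simulate_voxel(tissue, snr = Inf)
    sm <- vs$truth[vs$truth$b >= 6, c("b", "sbar")]
    fit <- fit_radius(sm, prot)
    expect_equal(fit$r, vs$r_eff_true, tolerance = 0.02)
  }
})

test_that("residual extra-cellular signal at b = 6 biases small radii upwards", {
  # with f < 1 the lower shell keeps a small extra-cellular contribution;
  # the induced overestimation is positive and fades as the true radius
  # (and hence the intra-axonal attenuation contrast) grows
  prot <- strong_shells()
  bias <- vapply(c(2, 3, 5), function(r0) {
    vs <- simulate_voxel(tissue_params(f = 0.7, dist = axon_point(r0)),
                         snr = Inf)
    fit <- fit_radius(vs$truth[vs$truth$b >= 6, c("b", "sbar")], prot)
    fit$r / r0 - 1
  }, numeric(1))
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.01)
})

test_that("broad radius distributions bias the single-radius fit downwards", {
  # the moment-ratio identity is a leading-order result: with strong
  # attenuation a broad Gamma law attenuates less than its r_eff point
  # equivalent, so the fitted radius falls below r_eff -- a documented
  # limitation, and the bias shrinks as the distribution narrows
  prot <- strong_shells()
  fit_for <- function(shape) {
    scale <- 3 / ((shape + 2) * (shape + 3) * (shape + 4) * (shape + 5))^(1 / 4)
    vs <- simulate_voxel(tissue_params(f = 1, dist = axon_gamma(shape, scale)),
                         snr = Inf)
    fit_radius(vs$truth[vs$truth$b >= 6, c("b", "sbar")], prot)$r
  }
  r_broad <- fit_for(2)
  r_mid <- fit_for(5)
  r_narrow <- fit_for(50)
  expect_lt(r_broad, r_mid)
  expect_lt(r_mid, r_narrow)
  expect_lt(r_narrow, 3 * 1.001)
  expect_gt(r_narrow, 3 * 0.97)
})

test_that("bundle datasets share ground truth across test-retest replicates", {
  cl <- cbind(seq(0, 80, length.out = 81), 0, 0)
  ds <- simulate_bundle_dataset(cl, n_streamlines = 12, spread = 5,
                                profile = function(s) 2 + s, sigma = 1 / 30,
                                seed = 11)
  tr <- simulate_test_retest(ds, seeds = c(101, 202))
  expect_identical(tr$test$smean_clean, tr$retest$smean_clean)
  expect_false(identical(tr$test$smean, tr$retest$smean))
  # swapping seeds swaps the noise realisations exactly
  tr2 <- simulate_test_retest(ds, seeds = c(202, 101))
  expect_identical(tr2$test$smean, tr$retest$smean)
  expect_identical(tr2$retest$smean, tr$test$smean)
  # sigma = 0 collapses any downstream TRV to zero
  ds0 <- simulate_bundle_dataset(cl, n_streamlines = 12, spread = 5,
                                 profile = function(s) rep(3, length(s)),
                                 sigma = 0, seed = 11)
  tr0 <- simulate_test_retest(ds0)
  p1 <- tract_profile(tr0$test$bundle, tr0$test$smean, ds0$shells,
                      ds0$voxel_dim, ds0$origin)
  p2 <- tract_profile(tr0$retest$bundle, tr0$retest$smean, ds0$shells,
                      ds0$voxel_dim, ds0$origin)
  expect_equal(trv(p1$r, p2$r), 0)
})

test_that("null-effect cohorts reject at the nominal rate and power grows with n", {
  null <- simulate_two_cohorts(0, 10, 7, n_replicates = 2000, seed = 31)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(null$rejection_rate - 0.05), 3 * se)
  p7 <- simulate_two_cohorts(12, 10, 7, n_replicates = 1000, seed = 32)
  p20 <- simulate_two_cohorts(12, 10, 20, n_replicates = 1000, seed = 33)
  expect_gt(p20$rejection_rate, p7$rejection_rate)
})
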