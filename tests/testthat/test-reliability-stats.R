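test_that("TRV reproduces the hand-worked example and its invariances", {
  expect_equal(trv(c(1, 2), c(1, 2)), 0)
  # pairs (1.0, 1.2) and (2.0, 1.8)
  expect_equal(trv(c(1.0, 2.0), c(1.2, 1.8)),
               100 * sqrt(pi / 2) * (0.2 / 1.1 + 0.2 / 1.9) / 2,
               tolerance = 1e-12)
  expect_equal(round(trv(c(1.0, 2.0), c(1.2, 1.8)), 2), 17.99)
  # scale invariance
  expect_equal(trv(3 * c(1.0, 2.0), 3 * c(1.2, 1.8)),
               trv(c(1.0, 2.0), c(1.2, 1.8)))
  expect_error(trv(c(1, -1), c(2, 1)), "zero pair mean")
})

test_that("TRV converges to sqrt(2) times the per-measurement CV", {
  set.seed(99)
  n <- 1e6
  cv <- 0.05
  test <- 1 + rnorm(n, 0, cv)
  retest <- 1 + rnorm(n, 0, cv)
  expect_equal(trv(test, retest), 100 * sqrt(2) * cv, tolerance = 0.01)
})

test_that("ICC(A,1) matches perfect agreement, disagreement, and the ANOVA oracle", {
  expect_equal(icc_a1(c(1, 2, 3), c(1, 2, 3))$icc, 1)
  neg <- icc_a1(c(1, 2, 3), c(3, 2, 1))
  expect_lt(neg$icc, 0)
  # from-scratch oracle through stats::aov mean squares
  icc_aov <- function(test, retest) {
    df <- data.frame(y = c(test, retest),
                     unit = factor(rep(seq_along(test), 2)),
                     sess = factor(rep(1:2, each = length(test))))
    ms <- anova(stats::aov(y ~ unit + sess, data = df))[["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- length(test); k <- 2
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
  expect_equal(neg$icc, icc_aov(c(1, 2, 3), c(3, 2, 1)), tolerance = 1e-10)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- 0.6 * a + rnorm(n, 0, 0.5)
    expect_equal(icc_a1(a, b)$icc, icc_aov(a, b), tolerance = 1e-10)
  }
})

test_that("ICC interpretation bands follow the published cut points", {
  set.seed(3)
  a <- rnorm(200)
  mk <- function(r) icc_a1(a, r * a + rnorm(200, 0, sqrt(1 - r^2)))
  expect_equal(icc_a1(1:10, 1:10)$band, "excellent")
  expect_equal(mk(0.62)$band %in% c("moderate", "good"), TRUE)
  low <- icc_a1(rnorm(100), rnorm(100))
  expect_equal(low$band, "poor")
})

test_that("ICC confidence interval covers a known reliability", {
  set.seed(17)
  rho <- 0.8
  hits <- 0
  for (i in 1:100) {
    u <- rnorm(2000, 0, sqrt(rho))
    a <- u + rnorm(2000, 0, sqrt(1 - rho))
    b <- u + rnorm(2000, 0, sqrt(1 - rho))
    ci <- icc_a1(a, b)
    if (ci$ci_lower <= rho && rho <= ci$ci_upper) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("Bland-Altman reproduces hand arithmetic and sign symmetry", {
  ba <- bland_altman(c(1.0, 2.0), c(1.1, 1.9))
  d <- c(100 * 0.1 / 1.05, -100 * 0.1 / 1.95)
  expect_equal(ba$differences[[1]], d, tolerance = 1e-10)
  expect_equal(ba$mean_diff_pct, mean(d), tolerance = 1e-10)
  expect_equal(ba$sd_diff_pct, sd(d), tolerance = 1e-10)
  expect_equal(ba$loa_upper - ba$mean_diff_pct, 1.96 * sd(d), tolerance = 1e-10)
  expect_equal(round(c(d, mean(d), sd(d)), 2), c(9.52, -5.13, 2.20, 10.36))
  # identical pairs
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ba0[1, 1:4]), c(mean_diff_pct = 0, sd_diff_pct = 0,
                                      loa_lower = 0, loa_upper = 0))
  # swapping test and retest negates the mean, keeps the SD
  ba_swap <- bland_altman(c(1.1, 1.9), c(1.0, 2.0))
  expect_equal(ba_swap$mean_diff_pct, -ba$mean_diff_pct)
  expect_equal(ba_swap$sd_diff_pct, ba$sd_diff_pct)
})

test_that("correlation matrix filters implausible voxels listwise", {
  set.seed(12)
  n <- 5000
  z <- rnorm(n)
  metrics <- tibble::tibble(
    fa = pmin(pmax(0.5 + 0.1 * z, 0), 1),
    md = 0.8 - 0.05 * z + rnorm(n, 0, 0.02),
    r_eff = 3 + rnorm(n)
  )
  m <- correlation_matrix(metrics)
  expect_equal(diag(m), c(fa = 1, md = 1, r_eff = 1))
  expect_equal(m[1, 2], m[2, 1])
  expect_lt(m["fa", "md"], -0.8)
  # voxels pushed outside the bounds are excluded
  metrics2 <- metrics
  metrics2$md[1:100] <- 99
  m2 <- correlation_matrix(metrics2)
  expect_equal(attr(m2, "n_used"), n - 100)
  expect_equal(unname(attr(m2, "excluded")["md"]), 100L)
  expect_error(correlation_matrix(metrics[, 1, drop = FALSE]), "two metrics")
})

test_that("known joint correlation is recovered through the matrix", {
  set.seed(13)
  n <- 1e4
  x <- rnorm(n)
  y <- -0.6 * x + rnorm(n, 0, sqrt(1 - 0.36))
  m <- correlation_matrix(tibble::tibble(r_eff = 3 + x, smean30 = 1 + 0.1 * y))
  expect_equal(m["r_eff", "smean30"], -0.6, tolerance = 0.02)
  # perfect anti-correlation
  m2 <- correlation_matrix(tibble::tibble(a = x, b = -x, c = x + 1))
  expect_equal(m2["a", "b"], -1)
})

test_that("density mask keeps the top quartile with ties retained", {
  mask <- density_mask(1:100, p = 75)
  expect_equal(sum(mask), 25)
  expect_true(all(which(mask) >= 76))
  expect_equal(sum(density_mask(c(0, 0, 1:10), p = 0)), 10)
  # permutation invariance of the retained set
  set.seed(4)
  d <- c(rep(0, 10), runif(90))
  perm <- sample(100)
  expect_equal(sort(which(density_mask(d, 75))),
               sort(perm[density_mask(d[perm], 75)]))
  # ties at the threshold are retained
  expect_equal(sum(density_mask(rep(5, 8), p = 75)), 8)
})

test_that("noncentral-t power analysis matches a quadrature oracle", {
  expect_equal(power_two_sample(0, 10, 20), 0.05, tolerance = 1e-10)
  p <- power_two_sample(18, 10, 14)
  # independent oracle: numerical integration of the noncentral-t density
  d <- 18 / (10 / sqrt(2)); ncp <- d * sqrt(7 / 2); df <- 12
  tcrit <- qt(0.975, df)
  dens <- function(x) suppressWarnings(dt(x, df, ncp)) # dt's 1e-8 tail note
  oracle <- integrate(dens, tcrit, Inf)$value + integrate(dens, -Inf, -tcrit)$value
  expect_equal(p, oracle, tolerance = 1e-6)
  expect_gte(p, 0.96)
  # monotonicities
  expect_true(all(diff(vapply(c(5, 10, 18, 25), power_two_sample,
                              numeric(1), trv_pct = 10, n_total = 14)) > 0))
  expect_true(all(diff(vapply(c(10, 14, 20, 40), function(n)
    power_two_sample(18, 10, n), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(8, 10, 14), function(tv)
    power_two_sample(18, tv, 14), numeric(1))) < 0))
  expect_error(power_two_sample(18, -1, 14), "positive")
})

test_that("required sample size inverts the power computation", {
  n <- required_n(18, 10, target_power = 0.96)
  expect_lte(n, 14)
  expect_gte(power_two_sample(18, 10, n), 0.96)
  if (n > 4) expect_lt(power_two_sample(18, 10, n - 2), 0.96)
})

test_that("reliability report bundles the paired statistics tidily", {
  set.seed(20)
  a <- 3 + rnorm(500, 0, 0.2)
  b <- a + rnorm(500, 0, 0.2)
  rep <- reliability_report(a, b, metric = "r_eff")
  expect_s3_class(rep, "reliability_report")
  td <- generics::tidy(rep)
  expect_true(all(c("trv_pct", "icc") %in% td$statistic))
  gl <- generics::glance(rep)
  expect_equal(gl$metric, "r_eff")
  expect_equal(gl$trv_pct, trv(a, b))
})
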