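test_that("arc-length resampling hits the requested spacing and preserves length", {
  b <- straight_bundle(matrix(0, 1, 2), length_mm = 100, n_pts = 11)
  rb <- resample_streamlines(b, max_step = 2.5)
  expect_equal(nrow(rb$streamlines[[1]]), 41)
  expect_equal(rb$streamlines[[1]][1, ], c(0, 0, 0))
  expect_equal(rb$streamlines[[1]][41, ], c(100, 0, 0))
  # idempotent in node spacing
  rb2 <- resample_streamlines(rb, max_step = 2.5)
  expect_equal(rb$streamlines[[1]], rb2$streamlines[[1]])
  # circular arc of radius 50: length preserved within 0.1%
  th <- seq(0, pi / 2, length.out = 200)
  arc <- new_bundle(list(cbind(50 * cos(th), 50 * sin(th), 0)))
  ra <- resample_streamlines(arc, max_step = 1)
  len <- sum(sqrt(rowSums(diff(ra$streamlines[[1]])^2)))
  expect_equal(len, 50 * pi / 2, tolerance = 1e-3)
  # zero-length streamlines are dropped with a message
  bz <- new_bundle(list(cbind(c(0, 100), 0, 0), cbind(c(5, 5), 0, 0)))
  expect_message(rz <- resample_streamlines(bz, 2.5), "dropping 1")
  expect_length(rz$streamlines, 1)
})

test_that("trilinear interpolation is exact on constant and affine fields", {
  dims <- c(8, 6, 5)
  vx <- c(2, 2, 2)
  const <- array(3.7, dims)
  nodes <- cbind(runif(50, 2, 14), runif(50, 2, 10), runif(50, 2, 8))
  expect_equal(unname(interpolate_at_nodes(const, nodes, vx)[1:50]),
               rep(3.7, 50))
  # voxel centre returns that voxel's value
  f <- array(rnorm(prod(dims)), dims)
  ctr <- matrix(c((3 - 0.5) * 2, (4 - 0.5) * 2, (2 - 0.5) * 2), 1)
  expect_equal(as.numeric(interpolate_at_nodes(f, ctr, vx)[1]), f[3, 4, 2])
  # affine field recovered exactly
  xs <- (seq_len(dims[1]) - 0.5) * 2
  lin <- array(rep(2 * xs + 1, prod(dims[2:3])), dims)
  got <- interpolate_at_nodes(lin, nodes, vx)
  expect_equal(unname(got[1:50]), 2 * nodes[, 1] + 1, tolerance = 1e-6)
  # out-of-bounds nodes are flagged, all-out errors
  far <- matrix(c(1e3, 1e3, 1e3), 1)
  res <- interpolate_at_nodes(f, rbind(ctr, far), vx)
  expect_equal(attr(res, "n_out_of_bounds"), 1)
  expect_true(is.na(res[2]))
  expect_error(interpolate_at_nodes(f, far, vx), "outside")
})

test_that("centerline of identical or symmetric streamlines is the obvious line", {
  pts <- cbind(seq(0, 80, 2), sin(seq(0, 80, 2) / 10), 0)
  b1 <- new_bundle(list(pts, pts, pts))
  cl <- compute_centerline(b1, n_points = 41)
  ref <- compute_centerline(new_bundle(list(pts)), n_points = 41)
  expect_equal(cl, ref, tolerance = 1e-10)
  # two parallel straight lines -> the midline
  b2 <- straight_bundle(rbind(c(-3, 0), c(3, 0)))
  cl2 <- compute_centerline(b2, n_points = 21)
  expect_equal(cl2[, 2], rep(0, 21), tolerance = 1e-10)
  expect_equal(cl2[, 1], seq(0, 80, length.out = 21), tolerance = 1e-6)
  # permutation invariance
  b3 <- straight_bundle(rbind(c(-3, 0), c(1, 2), c(2, -2)))
  b3r <- new_bundle(rev(b3$streamlines))
  expect_equal(compute_centerline(b3, 21), compute_centerline(b3r, 21))
})

test_that("zero-mean helical perturbations leave the axis recoverable", {
  s <- seq(0, 80, length.out = 81)
  phases <- seq(0, 2 * pi, length.out = 9)[-9]
  sl <- lapply(phases, function(ph) {
    cbind(s, 2 * cos(2 * pi * s / 40 + ph), 2 * sin(2 * pi * s / 40 + ph))
  })
  cl <- compute_centerline(new_bundle(sl), n_points = 81)
  rms <- sqrt(mean(cl[, 2]^2 + cl[, 3]^2))
  expect_lt(rms, 0.1)
})

test_that("equal-length segmentation partitions nodes and measures the cylinder", {
  offs <- as.matrix(expand.grid(y = c(-3, 0, 3), z = c(-3, 0, 3)))
  b <- resample_streamlines(straight_bundle(offs), max_step = 2.5)
  cl <- compute_centerline(b, n_points = 81)
  nodes <- segment_bundle(b, cl, N = 20)
  segs <- attr(nodes, "segments")
  expect_equal(nrow(segs), 20)
  expect_equal(segs$length, rep(4, 20), tolerance = 1e-6)
  expect_equal(sum(segs$length), 80, tolerance = 1e-6)
  # every interior node lands in exactly one segment (rows are unique nodes)
  expect_equal(anyDuplicated(nodes[, c("streamline", "node")]), 0)
  # cylinder radius equals the known maximal offset sqrt(3^2+3^2)
  expect_equal(max(segs$cyl_radius), sqrt(18), tolerance = 0.05)
  expect_true(all(nodes$weight > 0))
})

test_that("segment averaging applies inverse-distance streamline weights", {
  # two streamlines at distances 1 and 2 mm with values 1 and 4
  b <- resample_streamlines(straight_bundle(rbind(c(1, 0), c(-2, 0))),
                            max_step = 2.5)
  cl <- cbind(seq(0, 80, length.out = 81), 0, 0)
  nodes <- segment_bundle(b, cl, N = 20)
  vals <- ifelse(nodes$streamline == 1, 1, 4)
  avg <- segment_average(nodes, vals, N = 20)
  expect_equal(avg$sbar, rep(2, 20), tolerance = 1e-10)
  # constant values are returned unchanged regardless of weights
  avg2 <- segment_average(nodes, rep(5, nrow(nodes)), N = 20)
  expect_equal(avg2$sbar, rep(5, 20))
  expect_false(any(avg2$missing))
})

test_that("segment statistics are invariant to streamline order and rigid rotation", {
  set.seed(5)
  offs <- cbind(runif(12, -4, 4), runif(12, -4, 4))
  b <- resample_streamlines(straight_bundle(offs), max_step = 2.5)
  cl <- compute_centerline(b, 81)
  n1 <- segment_bundle(b, cl, N = 20)
  bperm <- new_bundle(b$streamlines[c(7:12, 1:6)], b$voxel_dim)
  n2 <- segment_bundle(bperm, compute_centerline(bperm, 81), N = 20)
  s1 <- attr(n1, "segments"); s2 <- attr(n2, "segments")
  expect_equal(s1$cyl_radius, s2$cyl_radius, tolerance = 1e-8)
  expect_equal(s1$n_nodes, s2$n_nodes)
  # rigid rotation of all coordinates
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  brot <- new_bundle(lapply(b$streamlines, function(s) s %*% R), b$voxel_dim)
  n3 <- segment_bundle(brot, compute_centerline(brot, 81), N = 20)
  s3 <- attr(n3, "segments")
  expect_equal(s3$cyl_radius, s1$cyl_radius, tolerance = 1e-6)
  expect_equal(s3$length, s1$length, tolerance = 1e-6)
})

test_that("tract profile recovers a constant radius along a noiseless bundle", {
  cl <- cbind(seq(0, 80, length.out = 81), 0, 0)
  ds <- simulate_bundle_dataset(cl, n_streamlines = 30, spread = 5,
                                profile = function(s) rep(3, length(s)),
                                sigma = 0, seed = 7)
  prof <- tract_profile(ds$bundle, ds$smean, ds$shells, ds$voxel_dim,
                        ds$origin)
  expect_s3_class(prof, "tract_profile")
  expect_equal(nrow(prof), 20)
  expect_equal(prof$r, rep(3, 20), tolerance = 1e-6)
  expect_equal(prof$beta, rep(ds$beta, 20), tolerance = 1e-6)
  expect_false(any(prof$flag))
})

test_that("tract profile tracks a linear radius trend within tolerance", {
  cl <- cbind(seq(0, 80, length.out = 81), 0, 0)
  lin <- function(s) 2 + 2 * s
  ds <- simulate_bundle_dataset(cl, n_streamlines = 30, spread = 5,
                                profile = lin, sigma = 1 / 100, seed = 8)
  prof <- tract_profile(ds$bundle, ds$smean, ds$shells, ds$voxel_dim,
                        ds$origin)
  truth <- lin((prof$segment - 0.5) / 20)
  expect_lt(max(abs(prof$r - truth) / truth), 0.05)
  expect_gt(cor(prof$segment, prof$r), 0.98) # monotone trend recovered
  # flipping reverses the profile
  prof_f <- tract_profile(ds$bundle, ds$smean, ds$shells, ds$voxel_dim,
                          ds$origin, flip = TRUE)
  expect_equal(prof_f$r, rev(prof$r))
})

test_that("segment averaging before fitting beats per-voxel fits on variance", {
  cl <- cbind(seq(0, 80, length.out = 81), 0, 0)
  ds <- simulate_bundle_dataset(cl, n_streamlines = 24, spread = 6,
                                profile = function(s) rep(3, length(s)),
                                sigma = 1 / 12, seed = 9)
  # per-voxel estimates inside the bundle core
  dims <- dim(ds$smean)[1:3]
  centers <- as.matrix(expand.grid(
    x = ds$origin[1] + (seq_len(dims[1]) - 0.5) * ds$voxel_dim[1],
    y = ds$origin[2] + (seq_len(dims[2]) - 0.5) * ds$voxel_dim[2],
    z = ds$origin[3] + (seq_len(dims[3]) - 0.5) * ds$voxel_dim[3]))
  core <- which(centers[, 1] > 10 & centers[, 1] < 70 &
                  sqrt(centers[, 2]^2 + centers[, 3]^2) < 4)
  r_vox <- vapply(core[1:40], function(i) {
    idx <- arrayInd(i, dims)
    sb <- ds$smean[idx[1], idx[2], idx[3], ]
    if (any(sb <= 0)) return(NA_real_)
    fit_radius(tibble::tibble(b = ds$shells$b, sbar = sb), ds$shells)$r
  }, numeric(1))
  prof <- tract_profile(ds$bundle, ds$smean, ds$shells, ds$voxel_dim,
                        ds$origin)
  expect_lt(sd(prof$r[3:18]), sd(r_vox, na.rm = TRUE))
})
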