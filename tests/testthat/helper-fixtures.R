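# Shared fixtures: strong-shell protocol and small geometric bundles.

strong_shells <- function() {
  dplyr::filter(make_connectom_protocol(), b >= 6)
}

# 1000-root, tight-tolerance evaluation of the cylinder sum: the
# independent oracle for the adaptive truncation
lnS_perp_oracle <- function(r, q, delta, Delta, D0 = 2.5, M = 1000) {
  if (r == 0 || q == 0) return(0)
  roots <- bessel_prime_roots(M)
  a2 <- roots^2
  tc <- r^2 / D0
  E <- -2 + 2 * exp(-a2 * delta / tc) + 2 * exp(-a2 * Delta / tc) -
    exp(-a2 * (Delta - delta) / tc) - exp(-a2 * (Delta + delta) / tc)
  s <- sum(2 * delta / (a2^2 * (a2 - 1)) + tc * E / (a2^3 * (a2 - 1)))
  -(2 * q^2 * r^4 / D0) * s
}

# straight bundle of parallel streamlines offset in y/z
straight_bundle <- function(offsets, length_mm = 80, n_pts = 41,
                            voxel_dim = c(2.5, 2.5, 2.5)) {
  sl <- lapply(seq_len(nrow(offsets)), function(i) {
    cbind(seq(0, length_mm, length.out = n_pts),
          offsets[i, 1], offsets[i, 2])
  })
  new_bundle(sl, voxel_dim = voxel_dim)
}
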