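# mraxon

Effective MR axon radius mapping from strong-gradient diffusion MRI, in R.

Axon radii (~1 um) sit far below MRI resolution, but with ultra-strong
diffusion gradients (~300 mT/m) the perpendicular signal attenuation of
water restricted inside axons becomes measurable in vivo. `mraxon`
implements the complete analysis for such experiments:

* **Forward model** — Gaussian-phase (van Gelderen) attenuation of spins in
  a cylinder, $\ln S_\perp \propto -q^2 r^4/D_0 \sum_m[\dots]$ over Bessel
  roots, with its Neuman wide-pulse limit
  $\ln S_\perp \approx -(7/48)\,q^2 r^4 \delta/D_0$, and the effective
  radius of a radius distribution,
  $r_{\rm eff} = (\langle r^6\rangle/\langle r^2\rangle)^{1/4}$.
* **Estimator** — the spherical mean at two strong shells
  (b = 6, 30 ms/um^2) follows $\bar S(b) = \beta\, b^{-1/2} S_\perp(r)$;
  the shell ratio of $\bar S \sqrt b$ is monotone in $r$, giving an exact
  two-shell solve with censoring flags at the resolution limit, plus
  Cramér–Rao precision bounds and pulse-timing/shell-placement
  optimisation.
* **Signal processing** — Rician maximum-likelihood spherical-harmonic
  spherical means with known noise level, scalar b-rescaling for gradient
  nonlinearity, and two-pass weighted-least-squares DKI on the b ≤ 2.5
  shells.
* **Along-tract analysis** — streamline resampling, trilinear map
  interpolation, bundle centerlines, 20 equal-length segments with
  cylindrical node membership and inverse-distance streamline weighting:
  signals are averaged per segment *before* the radius fit.
* **Reliability statistics** — test–retest variability
  $\mathrm{TRV} = \sqrt{\pi/2}\cdot\mathrm{mean}(|\Delta\theta|/\mu_\theta)$,
  ICC(A,1) with F-based confidence intervals and interpretation bands,
  Bland–Altman agreement, plausibility-screened Pearson correlation
  matrices, tract-density percentile masks, and exact noncentral-t power
  analysis.
* **Synthetic data** — a Connectom-style protocol (b = 0.5–30 ms/um^2,
  δ/Δ = 15/30 ms, G ≤ 273 mT/m), two-compartment voxel signals with Rician
  noise, fiber bundles with along-tract radius profiles, test–retest
  replicates and two-cohort study simulators, all with stored ground truth
  and seeds.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `plot_*()`/`autoplot()` companions.

## Worked example

Simulate one white-matter voxel under the strong-gradient protocol,
estimate its spherical means, and fit the effective radius:

```r
library(mraxon)
library(dplyr)

prot   <- filter(make_connectom_protocol(), b >= 6)
tissue <- tissue_params(f = 0.7, Da_par = 2, dist = axon_gamma(5, 0.356))
effective_radius(tissue$dist)   # 2.9996 um ground truth

vx <- simulate_voxel(tissue, snr = 30, seed = 7)
sm <- vx$data |>
  filter(b >= 6) |>
  group_by(b) |>
  group_modify(~ spherical_mean_ml(.x$signal,
                                   as.matrix(.x[, c("gx", "gy", "gz")]),
                                   sigma = vx$sigma)) |>
  ungroup()
sm
#>       b   sbar      se n_dirs l_max_used converged
#> 1     6 0.164  0.00304    120          6 TRUE
#> 2    30 0.0609 0.00215    240          6 TRUE

fit <- fit_radius(tibble::tibble(b = sm$b, sbar = sm$sbar,
                                 n_dirs = sm$n_dirs),
                  prot, sigma = vx$sigma)
glance(fit)
#>       r  beta residual_norm n_shells converged at_resolution_limit
#> 1  2.71 0.422             0        2 TRUE      FALSE
```

The fit reads 2.71 um against a generating effective radius of 3.0 um at
SNR 30 — the residual shortfall is the documented distribution-width bias
of the single-radius model for broad Gamma laws, not noise. A power
calculation for a cohort study using this metric:

```r
power_two_sample(diff_pct = 18, trv_pct = 10, n_total = 14)
#> 0.9916873
required_n(18, 10, target_power = 0.96)
#> 12
```

An 18% group difference at 10% voxelwise test–retest variability is
detectable with high power from about a dozen subjects.

For the full account of the model, the along-tract averaging procedure and
the synthetic generator, see `vignettes/effective-radius-mapping.Rmd`. A
thin command-line wrapper for voxelwise map fitting and power analysis
lives in `inst/scripts/mraxon-cli.R`.

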