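---
title: "Mapping the effective MR axon radius: model, estimator and reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the effective MR axon radius: model, estimator and reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mraxon)
library(dplyr)
```

## The measurement problem

Axon radii in human white matter are of order 1 um, three orders of
magnitude below the resolution of an MRI voxel. Diffusion-weighted MRI can
still sense them: water trapped inside an axon diffuses freely along the
fiber but is restricted across it, and at very strong diffusion weighting
the residual perpendicular signal attenuation carries the radius. With
ultra-strong gradients (~300 mT/m) this becomes measurable in vivo.
`mraxon` implements the full analysis chain for such an experiment —
forward model, estimator, precision bounds, along-tract averaging, and the
test–retest statistics used to judge whether the resulting maps are
reliable enough to serve as a biomarker — together with a synthetic-data
generator that stands in for scanner data.

## Signal model

At strong diffusion weighting (b >= 6 ms/um^2) the extra-cellular water,
which is mobile in every direction, has decayed away exponentially and the
direction-averaged (spherical mean, "powder average") signal of the
intra-axonal compartment follows

$$\bar S(b) = \beta\, b^{-1/2}\, S_\perp(r;\, q, \delta, \Delta),$$

where the $b^{-1/2}$ factor is the powder average of a zero-radius fiber
("stick") at large b, and $\beta$ is a nuisance amplitude that absorbs the
intra-axonal signal fraction $f$ and parallel diffusivity $D_{a\parallel}$
(for a stick population, $\beta = f\sqrt{\pi/4}/\sqrt{D_{a\parallel}}$; we
never invert this mapping, because $f$ and $D_{a\parallel}$ are not
separable from two shells). $S_\perp$ is the Gaussian-phase
(van Gelderen) attenuation of spins inside an impermeable cylinder of
radius $r$:

$$\ln S_\perp = -\frac{2 q^2 r^4}{D_0} \sum_{m=1}^{\infty}
  \frac{t_c}{\alpha_m^6(\alpha_m^2 - 1)}
  \left[ \frac{2\alpha_m^2\delta}{t_c} - 2
  + 2e^{-\alpha_m^2\delta/t_c} + 2e^{-\alpha_m^2\Delta/t_c}
  - e^{-\alpha_m^2(\Delta-\delta)/t_c}
  - e^{-\alpha_m^2(\Delta+\delta)/t_c} \right],$$

with $q = \gamma G$, $t_c = r^2/D_0$ the diffusion time across the
cylinder, and $\alpha_m$ the roots of $J_1'$. In the wide-pulse regime
($\delta \gg t_c$) this collapses to the Neuman law
$\ln S_\perp \approx -(7/48)\, q^2 r^4 \delta / D_0$; the package verifies
the 7/48 constant numerically from the root sum rather than assuming it.

Because the attenuation scales as $r^4$ and each axon contributes spins in
proportion to its cross-section ($r^2$), a whole distribution $P(r)$ of
radii is reported as a single **effective radius**

$$r_{\rm eff} = \left(\langle r^6\rangle / \langle r^2\rangle\right)^{1/4},$$

which is heavily weighted towards the largest axons. For a Gamma(α, γ)
law the closed form is $\gamma[(\alpha+2)(\alpha+3)(\alpha+4)(\alpha+5)]^{1/4}$.
The mean radius is *not* identifiable from $r_{\rm eff}$ alone:

```{r iso}
iso_effective_curve(3, c(1, 2, 5, 10))
```

All four distributions produce identical MR signals to leading order, yet
their mean radii span more than a factor of three.

## Units and constants

Lengths are in um, times in ms, gradients in mT/m, so b-values come out in
ms/um^2. The proton gyromagnetic ratio 2.6752e8 rad s^-1 T^-1 becomes
2.6752e-4 rad ms^-1 um^-1 per mT/m. The axoplasmic diffusivity $D_0$
defaults to 2.5 um^2/ms — a literature-typical value, configurable in
every function, since the experiment itself cannot constrain it.

## Estimator

The fit operates on $y = \bar S\sqrt b$, which removes $\beta$ from the
shell ratio: with the two strong shells (b = 6 and 30 ms/um^2) the ratio
$y_{30}/y_{6} = \exp[\ln S_\perp(r; 30) - \ln S_\perp(r; 6)]$ depends on
$r$ alone and is strictly monotone, so the estimate is a bracketed root
solve on [0, 10] um and $\beta$ follows in closed form. Ratios at or above
1 (no measurable differential attenuation) are censored to $r = 0$, and
impossibly steep decays to the 10 um bound; both raise a resolution-limit
flag, as does any estimate whose Cramér–Rao standard deviation exceeds
half the estimate itself. The 10 um bound is beyond anatomical
plausibility and simply keeps the bracket finite. With more than two
shells a bounded nonlinear least-squares fit over $(\log\beta, r)$ takes
over.

Precision is quantified by the Cramér–Rao lower bound under Gaussian noise
on per-shell spherical means (variance $\sigma^2/n_{\rm dirs}$ —
justified by averaging over many directions; Rician effects are handled
upstream at the directional stage). The model derivative in $r$ is
analytic; tests verify it against finite differences. `protocol_landscape()`
maps the bound over pulse timings $(\delta, \Delta)$ under the gradient
ceiling (273 mT/m) and an echo-time budget ($\delta + \Delta \le 66$ ms):
at fixed $\Delta$ the bound is best at the smallest gradient-feasible
$\delta$, and the timing pair (15, 30) ms used throughout sits within 25%
of the grid optimum. `optimize_shell_placement()` shows that a
direction-budget allocation optimized for the bound concentrates on the
extreme b-values, while uniform-in-G sampling wastes measurements at
intermediate shells.

## Spherical means, DKI, and screening

Per-shell spherical means are estimated as the order-zero coefficient of
an even spherical-harmonic expansion (order 6 by default, falling back
when directions are scarce) fitted by maximum likelihood under the Rician
magnitude distribution with known noise level. The fit starts at the
least-squares solution and converges at 1e-8 on the objective; a
non-converged fit is returned flagged, carrying its initialization. The
normalisation makes the reported value the average over the unit sphere.
The noise level is an input (map or scalar) — estimating it is a separate,
published problem that this package deliberately does not re-solve.

Gradient nonlinearities are handled as a scalar per-voxel rescaling of b
(applied consistently to $q^2$); directional variability of the
nonlinearity is not modeled. Shells are grouped with a 5% b-value
tolerance. DTI/DKI metrics for the between-metric correlation analysis are
fitted by two-pass weighted linear least squares on the b <= 2.5 ms/um^2
shells only, and the correlation analysis screens voxels listwise against
plausibility bounds (FA in [0,1], diffusivities in [0,4] um^2/ms, kurtosis
in [-1,10]) before computing Pearson coefficients.

## Along-tract averaging

Voxelwise estimates at feasible scan times are noisy. The along-tract
procedure compresses the spherical means — not the fitted radii — into 20
segments per tract before fitting:

1. take an oriented bundle of streamlines;
2. resample each streamline below the voxel size and interpolate the
   per-shell spherical-mean maps (trilinear) at every node;
3. form the bundle centerline (arc-length-normalised pointwise mean,
   smoothed with a symmetric moving average of window 5 — the simplest
   deterministic choice, implemented as a swappable strategy);
4. cut the centerline into 20 equal-length segments; the tangent at each
   segment midpoint defines a cylinder axis, nodes join the first segment
   whose projection interval contains them, and the cylinder radius is
   the maximal node distance to the axis;
5. average node signals per shell, weighting each streamline by the
   inverse of its mean perpendicular distance to the axis (floored at
   0.1 mm so on-axis streamlines cannot acquire infinite weight), then
   fit $(\beta, r)$ per segment.

Averaging signals before fitting is the design point: the spherical mean
is rotationally invariant, so modest within-segment curvature does not
corrupt the average, and the segment fit sees an effective noise level
reduced by roughly the square root of the node count.

## Reliability statistics

For paired test–retest estimates over $N$ units,

$$\mathrm{TRV} = \sqrt{\pi/2}\,\frac1N \sum_i
  \frac{|\Delta\theta(x_i)|}{\mu_\theta(x_i)},$$

which under Gaussian repeats with per-measurement coefficient of variation
$c$ converges to $\sqrt 2\, c$ — the package verifies this calibration by
simulation. ICC(A,1) (two-way mixed effects, single measurement, absolute
agreement) is computed from the ANOVA mean squares with the F-based 95%
confidence interval, banded as poor (< 0.5), moderate (0.5–0.75), good
(0.75–0.9) and excellent (> 0.9), applied to both the point estimate and
the CI lower bound. Bland–Altman summaries normalise differences by pair
means, in percent, with ±1.96 SD limits of agreement.

The power analysis converts a TRV into a per-measurement CV via
$c = \mathrm{TRV}/\sqrt2$ (the exact folded-normal consequence of the TRV
definition), forms Cohen's d, and evaluates exact noncentral-t power for a
two-sided two-sample t-test. An 18% group difference at 10% TRV reaches
power `r round(power_two_sample(18, 10, 14), 3)` with 14 subjects total;
the smallest even total achieving 0.96 is
`r required_n(18, 10, 0.96)`. The percentile tract-density mask retains
voxels at or above the p-th percentile of nonzero densities (ties kept);
p defaults to 75, and because "top 75% of the map" and "above the 75th
percentile" are both defensible readings of common usage, the percentile
is exposed as a parameter rather than fixed.

## What the synthetic generator emulates — and what it does not

`make_connectom_protocol()` reproduces a strong-gradient two-session human
protocol: shells at b = 0.5, 1, 2.5, 6, 30 ms/um^2 with 30/30/30/120/240
electrostatically relaxed directions, δ/Δ = 15/30 ms, 23 b = 0 images, and
the top shell at the 273 mT/m hardware ceiling. `simulate_voxel()` builds
directional signals from restricted cylinders (axial Gaussian times
Gaussian-phase radial attenuation per fiber, integrated over the radius
distribution with $r^2$ spin-count weighting by quadrature — so the
moment-ratio identity is a test outcome, not an input) plus an axially
symmetric extra-cellular tensor, and adds Rician noise through two
Gaussian channels. The default SNR of 30 at b = 0 is a typical
white-matter value for this scanner class. `simulate_bundle_dataset()`
voxelizes spherical-mean maps around a parametric centerline with a
prescribed $r_{\rm eff}(s)$ profile; map noise is Gaussian with variance
$\sigma^2/n_{\rm dirs}$, the central-limit consequence of averaging over
>= 120 directions. Test–retest replicates share the noiseless maps and
redraw noise.

Not emulated: imaging artifacts (Gibbs ringing, eddy currents, motion,
susceptibility distortion), spatially varying noise, gradient-nonlinearity
tensor fields, tractography errors, and partial voluming with grey matter
or CSF. Passing tests therefore demonstrate the statistical mechanics of
the pipeline under its own model, not robustness to the full mess of real
acquisitions.

## Numerical choices

* Bessel-derivative roots are bracketed on a fine grid and polished with
  `uniroot` at 1e-13, cached per session; the first five match tabulated
  constants at 1e-12.
* The cylinder root sum truncates adaptively when the next term falls
  below 1e-9 of the partial sum (at most 200 roots); against a 1000-root
  evaluation the relative error stays below 1e-8 across r in [0.25, 5] um.
  Terms are arranged so the $t_c \to 0$ limit is computed without overflow,
  making $r = 0$ and $G = 0$ exact zeros.
* The two-shell ratio solve treats ratios within 1e-12 of 1 as censored
  (float safety); segment boundaries assign ties to the lower index;
  degenerate (zero-length) streamlines are dropped with a message; empty
  segments are flagged missing rather than erroring.
* Electrostatic direction relaxation uses step-capped projected descent
  from a Fibonacci initialization — deterministic, no RNG.

## Scale of the shipped experiments

The packaged tests and the acceptance script run a deliberately small twin
of the full experiment: bundles of 24–40 streamlines (rather than 10,000)
over an 80 mm tract with a 6 mm radius, three test–retest noise replicate
pairs, 10^4 Monte-Carlo draws for estimator efficiency and 10^7 for the
moment-ratio check. The streamline count is chosen of the same order as
the number of voxels in the bundle cross-section so that streamlines
sample mostly distinct voxels, which keeps the node count an honest proxy
for the number of independent measurements per segment; the bundle noise
level is set from the Cramér–Rao bound to land the voxelwise TRV near the
10% regime the reliability analysis targets.

## Known limitations

* **Distribution-width bias.** $r_{\rm eff}$ is what the fit estimates
  only to leading order in the attenuation. At b = 30 with broad Gamma
  laws the distribution-averaged signal attenuates less than its
  $r_{\rm eff}$ point equivalent (Jensen), so the fitted radius
  undershoots — by ~10% for Gamma(α = 2) at $r_{\rm eff}$ = 3 um,
  vanishing as the distribution narrows. A test characterizes this bias;
  it is a property of the method, not a defect of the implementation.
* **Residual extra-cellular signal.** The b = 6 shell retains a small
  (< 5%) extra-cellular contribution at realistic fractions, which inflates
  small radii; the bias fades with increasing true radius.
* **Resolution floor.** Below roughly 2 um (at these gradients and SNR)
  the attenuation contrast drowns in noise; estimates there carry the
  resolution-limit flag and should be treated as censored, not as values.
* The centerline is a pointwise mean: adequate for tube-like bundles,
  wrong for sharply fanning ones.
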