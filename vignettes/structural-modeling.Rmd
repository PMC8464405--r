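---
title: "Structure-informed constitutive modeling of arterial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-informed constitutive modeling of arterial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberwall)
```

## The problem

Arteries are fiber-reinforced composites. Their passive mechanics is
dominated by two symmetric families of helical collagen fibers embedded in
a compliant ground substance, with the fiber architecture — a mean angle
$\alpha$ from the circumferential direction plus dispersion about it —
varying between vessels and with age. Lower-limb vessels such as the
superficial femoral artery additionally carry longitudinally oriented
elastic fibers in the external elastic lamina and circumferentially
oriented smooth muscle in the media. `fiberwall` implements a pipeline in
which that architecture is *measured* from fibrous-texture images and then
*held fixed* inside hyperelastic constitutive models fitted to planar
biaxial stress–stretch data, so that only genuinely material parameters are
estimated.

## Orientation model

A fiber direction is the unit vector
$\mathbf N(\Phi,\Theta) = \cos\Theta\cos\Phi\,\mathbf e_\theta +
\cos\Theta\sin\Phi\,\mathbf e_z + \sin\Theta\,\mathbf e_r$, with in-plane
angle $\Phi$ and out-of-plane angle $\Theta$. The orientation density
factorizes into independent in-plane and out-of-plane parts, each a von
Mises-type density:

$$\rho_{\rm ip}(\Phi) = \frac{\exp[a\cos 2(\Phi - \alpha)]}{I_0(a)},
\qquad
\rho_{\rm op}(\Theta) = 2\sqrt{\frac{2b}{\pi}}
\frac{\exp[b(\cos 2\Theta - 1)]}{\operatorname{erf}(\sqrt{2b})}.$$

$\rho_{\rm ip}$ is $\pi$-periodic (fibers are axes, not arrows) and
$\rho_{\rm op}$ is even with its peak in the wall plane. Their
normalizations are $\frac{1}{2\pi}\int_0^{2\pi}\rho_{\rm ip}\,d\Phi = 1$
and $\frac12\int_{-\pi/2}^{\pi/2}\rho_{\rm op}\cos\Theta\,d\Theta = 1$ (the
$\cos\Theta$ is the sphere measure). The concentrations $a, b \ge 0$ map to
scalar dispersions

$$\kappa_{\rm ip} = \frac12 - \frac{I_1(a)}{2 I_0(a)} \in [0, 1], \qquad
\kappa_{\rm op} = \frac12 - \frac{1}{8b} +
\frac14\sqrt{\frac{2}{\pi b}}\frac{e^{-2b}}{\operatorname{erf}(\sqrt{2b})}
\in [0, \tfrac12],$$

monotone in their arguments, with the perfect-alignment limit
$(\kappa_{\rm ip}, \kappa_{\rm op}) \to (0, \tfrac12)$ and isotropic limits
$\kappa_{\rm ip} \to \tfrac12$ (planar) and $\kappa_{\rm op} \to \tfrac13$.

Numerical care at the edges:

* $\kappa_{\rm op}$ is a 0/0 form at $b = 0$; below $b = 10^{-6}$ we use
  the series $\tfrac13 + \tfrac{4b}{45}$.
* The exponentially scaled Bessel functions underflow around
  $a \approx 2\times 10^5$; beyond $a = 10^4$ the ratio $I_1/I_0$ uses its
  asymptotic expansion $1 - \frac{1}{2a} - \frac{1}{8a^2} - \frac{1}{8a^3}$
  (agreement with the scaled form is ~$10^{-13}$ at the switch point).
* $\rho_{\rm ip}$ is evaluated in the scaled form
  $e^{a(\cos 2(\Phi-\alpha) - 1)}/(I_0(a)e^{-a})$ so that arbitrarily large
  concentrations do not overflow.

Because the two collagen families share properties and image profiles show
mirrored peaks at $\pm\alpha$, profile fitting uses the symmetric mixture
$\tfrac12[\rho_{\rm ip}(\Phi; a, \alpha) + \rho_{\rm ip}(\Phi; a, -\alpha)]$
with $\alpha$ folded into $[0^\circ, 90^\circ]$.

## From images to angular distributions

`preprocess_image()` applies, in order: clipping of saturated maxima at the
99.9% intensity quantile (white-noise specks from calcification or dust),
a $3\times3$ median filter, min–max normalization to $[0,1]$, a second
median pass, and a final contrast stretch. Kernel size and clip quantile
are configurable; the defaults are deliberate choices, since the upstream
processing chain is described qualitatively rather than parametrically in
the source literature for this method.

`orientation_distribution()` computes the 2-D FFT power spectrum after a
raised-cosine (Hann) window — without it, edge discontinuities smear power
into axis-aligned wedges — and sums power over angular wedges of width 5°
(half-open bins $[c - w/2, c + w/2)$, so no double counting; peak ties are
broken toward the smaller angle by first-match). Summation is restricted to
a radial band of 1/20 to 1/4 of the Nyquist frequency: the lower cut
removes DC leakage and illumination gradients, the upper cut pixel noise.
A sinusoidal grating's stripes at angle $\varphi$ put spectral power at
$\varphi \pm 90^\circ$, so spectral orientation is rotated by 90° to give
spatial fiber orientation; this convention is locked in by a grating test
and a rotation-equivariance test, since it is the classic source of silent
orientation bugs.

### Isotropy classification

An image plane is called isotropic when a first-order polynomial fitted to
the *cumulative* angular amplitude distribution explains at least
$R^2 = 0.9998$ of its variance — a uniform density has an exactly linear
cumulative curve, which makes the strict threshold interpretable (a line
fitted to the raw flat profile would have an undefined $R^2$). The
threshold is exposed as `r2_threshold` because it is a *resolution-matched*
constant: the cumulative statistic's sampling noise scales inversely with
the number of independent spectral samples per wedge, so the default suits
dense megapixel acquisitions (the study imaged 1024–2300 px planes),
while sparse synthetic renders at 256 px need a looser value (~0.985 for
the default renderer settings). The package's tests verify both regimes.
Isotropic planes are assigned concentration 0 and no peak angle.

### Aggregation

Per-image fits are combined by `aggregate_stack()`: the specimen mean
fiber angle is the mean of the anisotropic per-image peak locations (the
wording of the source on this estimator is ambiguous — it mentions using
the standard deviation of peak locations — so we report mean ± SD
explicitly); $\kappa_{\rm ip}$ and $\kappa_{\rm op}$ are computed from the
*mean* concentration parameters, with isotropic images contributing zeros
(configurable via `include_isotropic`, since inclusion is stated but not
unambiguous).

## Constitutive models

With the right Cauchy–Green tensor $\mathbf C$ and generalized structure
tensors
$\mathbf H_i = A\mathbf I + B\,\mathbf M_i\otimes\mathbf M_i +
(1 - 3A - B)\,\mathbf M_n\otimes\mathbf M_n$, where $A = 2\kappa_{\rm op}
\kappa_{\rm ip}$ and $B = 2\kappa_{\rm op}(1 - 2\kappa_{\rm ip})$, the
two-fiber strain energy is

$$\Psi = \frac{c_2}{2}(I_1 - 3) + \sum_{i=1,2}
\frac{k_1}{2k_2}\left\{\exp[k_2 E_i^2] - 1\right\},
\qquad E_i = \mathbf H_i : (\mathbf C - \mathbf I).$$

Under planar biaxial stretch with incompressibility
($\lambda_r = 1/(\lambda_\theta\lambda_z)$) and a traction-free radial face
($\sigma_{rr} = 0$ eliminates the Lagrange pressure), the Cauchy stresses
are

$$\sigma_{\theta\theta} = [c_2 + 4(A + B\cos^2\alpha)\,\psi']\lambda_\theta^2 - p,
\quad
\sigma_{zz} = [c_2 + 4(A + B\sin^2\alpha)\,\psi']\lambda_z^2 - p,$$

with $p = [c_2 + 4(1 - 2A - B)\,\psi']\lambda_r^2$ and
$\psi' = k_1 E \exp(k_2 E^2)$.

The four-fiber model adds perfectly aligned longitudinal elastin
($\alpha = \pi/2$, strain $\lambda_z^2 - 1$) and circumferential smooth
muscle ($\alpha = 0$, strain $\lambda_\theta^2 - 1$), each with its own
$(k_1, k_2)$ pair, and carries a $k_1/(4k_2)$ energy prefactor for all
fiber terms (hence stress coefficients of 2 rather than 4 on the collagen
term). Two printed-form ambiguities were resolved by re-deriving the
stresses from the energy: the bracket placement in the four-fiber
$\sigma_{\theta\theta}/\sigma_{zz}$ expressions (all stiffness terms
multiply $\lambda_\theta^2$, resp. $\lambda_z^2$), verified against central
finite differences of $\Psi$ at tolerance $10^{-6}$; and the prefactor
convention, which makes the two-fiber model a strict special case under the
mapping $(c_2, k_1, k_2) \mapsto (c_4 = c_2, k_1^{\rm col} = 2k_1,
k_2^{\rm col} = k_2)$ with elastin and muscle switched off — tested
explicitly.

No tension–compression switch is applied to the fiber terms: the model
equations as published contain none, and the biaxial stretch ranges used
keep the fiber strains nonnegative in practice. The assumptions to keep in
mind: incompressibility, no shear (stretches aligned with the material
axes), quasi-static response (no viscoelasticity), a single homogenized
wall (no layer separation), and no residual stress.

## Fitting

`fiber_fit()` minimizes
$e = \sum_i (\sigma_{\theta\theta}^{\exp,i} - \sigma_{\theta\theta}^{th,i})^2 +
(\sigma_{zz}^{\exp,i} - \sigma_{zz}^{th,i})^2$ (kPa²) by
Levenberg–Marquardt (via `minpack.lm`), with all parameters bounded below
by zero (material stability; every published estimate for this tissue is
nonnegative) and the structural constants fixed. Because the exponential
laws produce local minima, the optimizer restarts from 20 log-uniform
random initial points by default ($10^{[-2,3]}$ for stiffness-like
parameters, $10^{[-2,2]}$ for exponents); convergence uses a relative
cost-change tolerance of $10^{-10}$ and at most 2000 residual evaluations
per start. Goodness of fit is the standard per-direction coefficient of
determination $R^2 = 1 - SS_{\rm res}/SS_{\rm tot}$ with squared terms —
the printed form of this formula in the source omits the squares, which is
dimensionally inconsistent for a determination coefficient, so the
standard definition is used.

`bootstrap_fit()` resamples individual stress–stretch records with
replacement (a per-protocol block bootstrap is available, since the
resampling unit is not specified in the source), refits each resample from
a randomized initialization near the point estimate, and selects, per
parameter, the highest-density mode of the marginal distribution (how the
original analysis chose "the global minimum" from the distributions is
unstated; a best-SSE alternative is provided).

## What the synthetic generators emulate — and what they do not

`make_protocols()` reproduces the 21-protocol stretch-controlled battery:
circumferential:longitudinal ratios 1:0.1–1:0.9 and 0.9:1–0.1:1 in 0.1
steps, with three equibiaxial 1:1 runs at the beginning, middle and end.
Paths are discretized at 50 points by default; strain rate is irrelevant to
the quasi-static model and ignored. `simulate_biaxial()` adds 2%
multiplicative plus 0.5 kPa additive Gaussian noise by default — a typical
load-cell/marker-tracking error scale, chosen here since measurement noise
is not quantified in the source.

`render_fiber_image()` draws straight (optionally sinusoidally undulated)
bright fiber chords whose orientations are sampled from the ±α von Mises
mixture (rejection sampling; Gaussian approximation with
$sd = 1/(2\sqrt a)$ above $a = 100$), rasterized by bilinear splatting
with a slight separable blur for thickness, over Gaussian background
noise. Out-of-plane images use the same renderer with angles from
$\rho_{\rm op}$; consistently, `fit_outofplane()` fits wedge amplitudes to
$\rho_{\rm op}(\Theta)$ directly, so the $\cos\Theta$ sphere measure enters
only the normalization identity, not the round trip. Undulation defaults
to zero because the von Mises density describes chord orientations;
waviness is a morphological option whose default wavelength (128 px) keeps
the modulation outside the wedge-filter band.

These generators validate *recovery*: that the pipeline returns the
orientation statistics and material parameters it was given. They do not
emulate real SHG imagery — no depth attenuation, no fiber crimp
heterogeneity, no layer boundaries, no partial-volume mixing of elastin
autofluorescence — so passing tests demonstrate internal consistency and
identifiability, not imaging-hardware robustness. Likewise the cohort
generator (`synth_cohort()`) imposes a clean linear age trend with
Gaussian scatter; it supports power/recovery checks of the statistics, not
biological inference.

## Problem sizes and runtime choices

The test suite runs desk-scale versions of every property: stretch paths at
6–10 steps per protocol (≈250–420 stress points per dataset) instead of the
tens of thousands of points of a full experimental record; 20 replicates
for noisy-recovery medians; 10×60 bootstrap replicates for the coverage
check; 256 px renders (3–4 per stack) for orientation recovery and a single
2048 px white-noise image for the isotropy limit. These sizes were chosen
so the full suite completes in about a minute while keeping every statistic
comfortably inside its tolerance; all scale parameters are function
arguments, so full-scale runs are one argument away.

## Known limitations

* The isotropy threshold is resolution-dependent (see above); applying the
  strict default to sparse or small images classifies everything
  anisotropic.
* Wedge filtering measures orientation of *texture energy*; fibers
  contribute in proportion to their spectral power, not their count, so
  strongly varying fiber brightness biases the concentration estimate.
* The bootstrap treats records as exchangeable; serially correlated noise
  within a protocol calls for the block variant.
* The models exclude shear, residual stress, viscoelasticity, active
  muscle tone and layer-specific mechanics by design.
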