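---
title: "From lens profile to functional classification: methods behind iolbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lens profile to functional classification: methods behind iolbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`iolbench` turns a description of a diffractive trifocal intraocular lens
into a predicted clinical picture: visual-acuity defocus curves per pupil
diameter and the depth-of-field functional classification derived from
them. This vignette explains the model at each stage, the parameters that
matter, the numerical choices, and what the simulation does and does not
capture.

## The diffractive lens model

A multifocal diffractive surface is periodic in the squared radial
coordinate. We model the surface phase at the design wavelength
$\lambda_0$ (550 nm) as a truncated harmonic series

$$\phi(r) \;=\; \sum_k a_k \sin\!\left(k\,\frac{2\pi r^2}{T} + \theta_k\right),$$

restricted to the annular diffractive zone between 1.40 mm and 6.0 mm
diameter. Because $\exp(i\phi)$ is periodic in $u = r^2$ with period $T$,
it decomposes into Fourier orders $c_n e^{i n 2\pi r^2 / T}$, and the term
$n\,2\pi r^2/T$ is exactly a quadratic (defocus) phase of power
$P_n = 2 n \lambda / T$. Choosing $T = 2\lambda_0 / \Delta$ therefore
spaces consecutive orders by $\Delta$ = 1.80 D at the IOL plane: order
−1 is the far focus, order 0 the intermediate focus (+1.80 D add) and
order +1 the near focus (+3.60 D add). The surface imprints a fixed
optical path difference, so at wavelength $\lambda$ the phase amplitudes
scale by $\lambda_0/\lambda$ and the order powers by $\lambda/\lambda_0$ —
the usual chromatic dispersion of diffractive adds. The refractive base
power is treated as achromatic.

The fraction of light in order $n$ is $|c_n|^2$, computed by FFT of
$e^{i\phi}$ sampled over one period (4096 samples). For a single harmonic
of amplitude $m$ the Jacobi–Anger expansion gives $|c_n|^2 = J_n(m)^2$;
the test suite holds the numeric decomposition to this closed form at
$10^{-6}$, and to energy conservation $\sum_n |c_n|^2 = 1$ at $10^{-6}$.

**Calibration.** Two harmonics are the minimal form able to produce an
asymmetric far/intermediate/near split. `calibrate_lens()` fits
$(a_1, a_2, \theta_2)$ by Nelder–Mead from the fixed start
$(1.2, 0.3, 0)$ ($\theta_1$ is fixed at 0: shifting the profile origin is
immaterial), minimizing the squared deviation of the achieved split from
the target. The optimizer is deterministic, so calibration is reproducible
bit for bit and needs no random seed.

**Normalized split.** The manufacturer's 43/21/36% distribution sums to
exactly 100%, but no pure-phase profile can put all light into three
orders (the calibrated profile leaves roughly 16% in orders $|n| \ge 2$).
We therefore interpret quoted light distributions as the split *among the
three design foci*, i.e. $|c_n|^2 / \sum_{m=-1}^{1} |c_m|^2$, which is
what `focus_split()` returns and what the ±0.02 calibration tolerance
applies to. Absolute efficiencies remain available from
`order_efficiencies()`.

**Central zone.** Inside the 1.40 mm inner diameter the surface is purely
refractive. Which focus that zone feeds is not derivable from the lens
description. We assign it the *intermediate* (order 0) power — the
refractive base is then one continuous power across the whole aperture,
which is the natural reading of "order 0 carries the base". The
alternative (`central_zone_role = "far"`) is implemented; it makes the
central zone a second coherent far-focused element whose defocused field
interferes with the focused annulus order 0 and visibly splits the
intermediate through-focus peak away from the labelled +1.80 D add, which
is why it is not the default.

## The virtual bench

The physical bench this emulates — Badal optometer, pupil relay, pinhole
object, camera — exists to deliver a controlled object vergence at the
IOL with an adjustable artificial pupil. We inject exactly that quantity
analytically: for vergence $d$ (diopters, the defocus-curve axis from
+1.0 to −4.0 D in 0.1 D steps) the pupil phase receives a quadratic
wavefront $W(r) = \tfrac{1}{2}(d + d_0)\,r^2$, where $d_0$ is the base
offset (+1.80 D wherever order 0 carries the intermediate focus), so that
diffraction order $n$ comes to focus at $d = -1.8 - 1.8n \cdot
\lambda/\lambda_0$: far at 0 D, intermediate at −1.8 D, near at −3.6 D.

The aperture is a circular mask with a one-pixel linear ("grey-pixel")
edge to suppress pixelation error. Spherical aberration enters as a
Zernike $Z_4^0$ wavefront whose coefficient is −0.1 µm at 6 mm, rescaled
to aperture $p$ by the standard $(p/6)^4$ factor (the balanced-polynomial
form at each aperture; the induced-defocus difference with plain cropping
is far below the 0.1 D grid step at these amplitudes). The artificial
cornea is treated as aberration-free and achromatic.

The PSF is the squared modulus of the FFT of the pupil field; the OTF is
the FFT of the PSF, normalized at zero frequency; the 2-D modulation
surface is reduced to a 1-D MTF by averaging over orientation in radial
frequency bins one frequency-sample wide (the simulated lens is
rotationally symmetric, so this is a noise-free radial profile; for
measured, possibly astigmatic data the average is rotation-robust).
Frequencies are expressed in lp/mm at the image plane through the
effective focal length, default 16.67 mm — a parameter that directly
scales MTFa and therefore the acuity predictions, which is why the
acceptance checks pin it.

**Sampling.** The grid is $1024^2$ with a pupil-plane extent of 4× the
largest simulated aperture. The incoherent-cutoff Nyquist condition
reduces, independently of wavelength, to extent ≥ 4 × aperture, so the
default sits exactly on the boundary and is asserted non-strictly at
configuration time. At the acceptance geometry (3 mm pupil, 12 mm extent)
the MTF frequency sampling is ≈ 1.3 lp/mm and the diffraction-limited MTF
agrees with the circular-aperture closed form
$\tfrac{2}{\pi}(\arccos s - s\sqrt{1-s^2})$, $s = \nu/\nu_c$, to better
than 0.01 absolute below 50 lp/mm.

## MTFa and photopic weighting

`mtfa()` is a composite trapezoid over the native frequency grid from 0
to 50 lp/mm, with the endpoint linearly interpolated when 50 lp/mm falls
between samples; no smoothing is applied anywhere. The polychromatic
value combines the five wavelengths with the photopic luminosity
coefficients (0.038, 0.323, 0.995, 0.631, 0.107 for 450–650 nm). Those
coefficients sum to 2.094, and whether the original analysis divided by
that sum is not stated; we normalize (weighted mean) so the polychromatic
MTFa stays commensurate with the monochromatic scale the prediction
models were built on. `polychromatic_mtfa(..., normalize = FALSE)` gives
the raw weighted sum for sensitivity checks.

## Acuity prediction models

Six empirical models map MTFa to logMAR acuity: exponential-decay
(Vega 2018, Fernández 2019b, Armengol 2020b), linear (Fernández 2019a)
and inverse-MTFa forms (Alarcón 2016, Armengol 2020a). Models built under
monochromatic green light receive the 550 nm MTFa column; models built
under polychromatic light receive the weighted column (`input` can force
either). Vega 2018 carries a floor clamp at 0.00 logMAR, reflecting the
ceiling effect of clinical datasets that never recorded acuities better
than 0.0; the other models are unclamped. All models are validated at
load time to be nonincreasing in MTFa on (0, 50], and the inverse forms
reject MTFa = 0 with a singularity error rather than returning infinity.

**Coefficient provenance.** The original publications' coefficient values
are not redistributable within this package, so the shipped registry
(`va_models_synthetic.json`, note the filename) contains *synthetic
representative coefficients*: fixed a priori to reproduce the documented
qualitative behaviour (acuity ≈ 0 logMAR above MTFa ≈ 25–30, ≈ 0.2 logMAR
near MTFa ≈ 7, steep degradation below 5, the Vega ceiling, the shallow
slope of the linear Full-DOFi-trained model) and frozen before any
simulation was run. Absolute predicted acuities therefore carry the
models' *shape*, not their published parameterization; users with access
to the original coefficients can drop in their own registry via
`va_models(path = ...)` without code changes.

## Spectacle-plane conversion and classification

Clinical defocus curves are produced by trial lenses at the spectacle
plane, so predicted curves are re-axed before classification. For each
IOL-plane vergence we solve (by monotone root finding at $10^{-12}$
tolerance) for the spectacle-lens power whose paraxial vergence chase —
12 mm vertex in air, +27.8 D bench cornea, 4 mm of aqueous (n = 1.336) to
the IOL — reproduces that vergence error. With the bench cornea the
−4.0 D grid edge maps to ≈ −3.54 D at the spectacle plane; the
physiological preset (43 D cornea) compresses further. A consequence is
that the −2 to −4 D near search window is clipped at the grid edge; the
clipping is flagged on the result rather than treated as an error, since
the classification windows were defined on exactly such converted curves.

`dofi()` walks from 0 D toward near and returns the first
linearly-interpolated crossing of the 0.2 (or 0.3) logMAR threshold;
multifocal curves can re-enter the threshold band, the range definition
does not address re-entry, and `crossing = "last"` is available. A curve
that never crosses within the grid returns the grid extent flagged
`grid_bounded`. `delta_va()` is (worst acuity in −0.5…−2 D) − (best in
−2…−4 D), clamped at 0, matching the exact zero entries of published
tables for small pupils. The category bands are applied with the
inequality directions Continuous < 0.05 ≤ Smooth < 0.14 ≤ Steep, and
Partial strictly below 2.3 D.

## What the simulation does and does not emulate

The generator reproduces the study conditions: the trifocal order
structure and adds, the 43/21/36 split at 3 mm, the −0.1 µm spherical
aberration, five discrete wavelengths with photopic weights, the defocus
grid, and pupils 1.5–5.5 mm. It does **not** include: the pupil-adaptive
radial apodization of the real lens (our split is radius-independent, so
large-pupil behaviour is harsher than the adaptive design — visible as
Partial cells at 4.5 mm in the worked example), lens tilt/decentration,
corneal chromatic aberration, the 30 µm pinhole's finite size (an ideal
point object is assumed), scatter, or camera noise. Monochromatic
coherent interference between the refractive central zone and the
diffractive orders is physical and retained; it is the reason the near
peak can land one 0.1 D grid step away from the nominal add. Passing
tests on this generator demonstrate the correctness of the optics,
metrics and classification machinery under these idealized conditions,
not agreement with any particular physical bench.

## Numerical choices and problem sizes

- Grid $1024^2$, extent 4× the largest aperture; per-(wavelength, defocus)
  cell two $1024^2$ FFTs (~0.5 s each cell), so the full five-wavelength,
  51-step sweep at one pupil runs in ~2 minutes.
- Unit and property tests run on $128^2$–$512^2$ grids with coarser
  defocus grids: every physical check used there (closed-form MTF,
  Parseval, Bessel oracles, Airy radius) is grid-size-independent, and the
  $512^2$ tolerance (0.01 absolute on MTF) is the same one used at full
  resolution in the acceptance file.
- Calibration: two sequential Nelder–Mead runs (restart at the optimum)
  with `reltol` $10^{-14}$; residual tolerance ±0.02 per order.
- Peak finding on through-focus curves uses strict local maxima with a
  ripple floor at 10% of the curve maximum; ties between equal-height
  neighbours resolve to the less myopic sample.
- Degenerate inputs fail loudly: all-zero PSFs (undefined MTF
  normalization), MTFa grids not covering 50 lp/mm, curves whose far
  acuity already fails the threshold, non-uniform defocus grids in
  exchange CSVs, comma-decimal locale files.

## Known limitations

Absolute MTFa levels depend on the effective focal length and on the
fraction of stray light in high diffraction orders, so predicted acuities
should be compared *between* configurations rather than read as clinical
point estimates; the synthetic model coefficients add a second layer of
the same caveat. The vergence-chase spectacle conversion is one defensible
choice among several used in practice (fixed-factor scalings exist); it
is exposed via `plane_conversion()` precisely so its effect can be
examined.
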