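---
title: "Single-image phase retrieval for edge-illumination X-ray imaging: model, filter and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-image phase retrieval for edge-illumination X-ray imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiphase)
```

## The imaging problem

Edge illumination (EI) is an X-ray phase-contrast technique in which a
narrow aperture shapes the beam before the sample and a second, partially
misaligned aperture sits in front of the detector. Refraction in the
sample shifts the beam vertically at the detector plane by
$z\,\Delta\theta_y$, where $z$ is the object-to-detector distance and
$\Delta\theta_y = \tfrac{1}{k}\,\partial_y \Phi$ is the refraction angle
($k$ the wavenumber, $\Phi$ the phase shift). The misaligned aperture
converts that shift into an intensity change through the *illumination
curve* $C(y_e)$ — the fraction of the unperturbed beam that enters the
detector aperture as a function of the aperture offset $y_e$. Along the
direction $x$ parallel to the slits the recorded signal is instead that of
near-field free-space propagation, described by the transport-of-intensity
equation. A single acquired image therefore mixes attenuation, refraction
along $y$, and propagation contrast along $x$.

For a homogeneous object with refractive index $n = 1 - \delta + i\beta$,
thickness map $t(x, y)$, attenuation coefficient $\mu = 2k\beta$ and
transmission $T = e^{-\mu t}$, the normalized signal at a working point
$(y_e, C_0 = C(y_e), C_1 = C'(y_e))$ in the linearized regime is

$$
S_n = \left[\, T \;+\; z\,\frac{C_1}{C_0}\, T\,\Delta\theta_y
\;-\; \frac{z}{k}\,\partial_x\!\left(T\, \partial_x \Phi\right) \right]
\otimes_x \mathrm{LSF}_x ,
$$

where $\mathrm{LSF}_x$ is the system line spread function along $x$ only:
in EI, source blur is already encoded in the measured shape of the
illumination curve and the detector point spread function does not affect
the $y$ signal, so the $y$ direction is never blurred.

With $\Phi = -k\,\delta\,t$, every term above is a derivative of the same
quantity $e^{-\mu t}$ (using $T\,\partial t = -\tfrac{1}{\mu}\,\partial
e^{-\mu t}$), and the model collapses, in Fourier space, to

$$
\mathcal{F}\{S_n\} \;=\; D(\xi_x, \xi_y)\; \mathcal{F}\{e^{-\mu t}\},
\qquad
D = \mathrm{MTF}_x(\xi_x)\,\Big[\, 1 + A\,\xi_x^2 +
i\,A\,\tfrac{C_1}{C_0}\,\xi_y \,\Big],
$$

with the single coefficient
$A = z\delta/\mu = \tfrac{z}{2k}\,\tfrac{\delta}{\beta}$ (units m²).
The thickness follows from one image by

$$
t = -\frac{1}{\mu}\,
\ln \mathrm{Re}\,\mathcal{F}^{-1}\!\left[\frac{\mathcal{F}\{S_n\}}{D}\right],
$$

and, under the weaker assumption that only the *ratio* $\delta/\beta$ is
constant, the projected electron density follows from the same filtered
image as $\rho_{e,p} = -\ln(\cdot)/\gamma$ with
$\gamma = 2k\sigma/(\delta/\beta)$ and
$\sigma = r_e\lambda^2/2\pi$ (`electron_density_scale()`). Because
$|D| \ge \mathrm{MTF}_x > 0$ everywhere and $D(0,0) = 1$, the filter never
diverges: it behaves as a low-pass on noise while leaving the zero
frequency untouched, the attenuation signal acting as a point-wise
regularizer. The filter's key advantage over one-dimensional integration
of a separately retrieved refraction image is the absence of the
column-wise streak artefacts that integration produces from noise; the
package ships that classical two-image pipeline (`two_image_retrieval()`
plus `integrate_refraction()`) as the comparison baseline, with
`streak_index()` quantifying the column anisotropy of a residual.

## Sign and frequency conventions

The public quantities are tied together by one convention, enforced
package-wide and pinned by round-trip tests rather than by any single
formula:

* $y_e$ is the height of the beam-profile centre above the *lower* edge of
  the detector aperture. On the default lower-edge branch $C_1 > 0$ and an
  upward refraction shift increases the counts; the unexpanded signal is
  $T\,C(y_e + z \Delta\theta_y)/C_0$ (`mode = "exact-curve"`).
* $\Phi = -k\delta t$, $\Delta\theta_y = -\delta\,\partial_y t$.
* Fourier transforms use the $e^{-i\xi\cdot r}$ kernel, so
  $\mathcal{F}\{\partial_y f\} = +i\xi_y \mathcal{F}\{f\}$. On even grids
  the odd-order derivative multiplier at the Nyquist frequency is set to
  zero (the standard convention for spectral derivatives), which keeps $D$
  Hermitian: real images map to real images, and the spectral simulator /
  retrieval pair inverts to machine precision.

## Parameters that matter

| Parameter | Meaning | Unit | Typical value |
|---|---|---|---|
| `delta`, `beta` | refractive index decrement / imaginary part | — | PET at 27 keV: 4.09e-7, 7.83e-11 |
| `z_od` | object-to-detector distance | m | 3.85 (wire bench), 0.30 (petal bench) |
| `step_y`, `step_x` | scan step / pixel size | µm | 20 / 46, or 1.6 / 1.6 |
| `lsf_fwhm_x` | LSF FWHM along x | µm | of the order of the pixel |
| `fraction` | working-point illumination | — | 0.5 |
| `a1`, `a2`, `sigma_src` | aperture widths, source blur | µm | 20, 250, 0.28 |
| `eps` | clip floor before the logarithm | — | 1e-8 |
| `pad`, `pad_band` | padding style / edge-band width | — | `"replicate"`, 8 |

`delta/beta` is deliberately exposed as a single tunable scalar in
`retrieve_electron_density()`: for mixed biological samples it is an
effective parameter, adjusted for image quality, and only the prefactor
$\gamma$ uses the absolute scale.

The two benchmark constructors freeze the study conditions used
throughout the tests: `wire_benchmark_geometry()` /
`wire_benchmark_curve()` describe a synchrotron slit setup at 27 keV
(20 µm and 250 µm apertures, 3.85 m propagation, 20 µm scan step, 46 µm
pixels, source blur of 0.28 µm — a 24 µm FWHM vertical source projected
over 3.85 m from 140 m); `petal_benchmark_geometry()` /
`petal_benchmark_curve()` describe a high-resolution virtual-edge
configuration at 9.7 keV (3 µm aperture, single edge, 0.30 m propagation,
1.6 µm sampling).

## Numerical design choices

**Padding.** The $y$ part of the inverse filter,
$1/(1 + i c_1 \xi_y)$ with $c_1 = A\,C_1/C_0$, has a one-sided exponential
kernel of decay length $c_1$ — 7.3 mm for the PET wire bench, *longer than
the field of view*. Padding choices that are innocuous for symmetric
(Paganin-type) filters are not innocuous here. Mirror padding reflects the
signal evenly, while the model requires the refraction term to change sign
under reflection; the resulting inconsistent copies in the margins are
smeared across the whole frame by the long kernel (measured: +7% on the
retrieved wire peak). The default is therefore *edge replication* to the
next power of two with at least a 25% margin per side. The replicated
value is the mean over an edge band (`pad_band = 8` samples) rather than
the raw edge sample: under Poisson noise, copying one noisy edge pixel
across a margin longer than the kernel would inject column-constant noise
straight into the filter's passband (measured: roughly a threefold RMSE
inflation at 1000 photons/pixel). `pad = "mirror"` and `pad = "none"`
(periodic) remain available; `pad = "none"` is the exact inverse of the
spectral simulator and is what the machine-precision round-trip test
uses.

**Derivative stencils.** The spatial-domain simulator uses central
differences (one-sided at the frame edges); the retrieval uses true
spectral derivatives. These two discretizations cross-validate each other:
`simulate_mixed_spectral(..., stencil = "central")` evaluates the compact
form with the DFT symbols of the central-difference stencils
($\sin(\xi h)/h$), and matches the spatial simulator to ~1e-8 RMS on
smooth compact-support phantoms. The identity that regroups the physical
form into the compact form holds discretely only to
$O(\mu h^2 t' t'')$, so agreement on steep objects (the wire's edges) is
limited to ~5e-4 RMS — a property of the discretization, not a bug; the
retrieval accuracy tests quantify the end-to-end consequence instead
(wire peaks recovered to 0.1–0.8%).

**Clipping and realness.** Noise can push the filtered image to or below
zero; the logarithm argument is clipped at `eps = 1e-8` and the clipped
fraction is reported in the `"retrieval_log"` attribute (an error is
raised only when *every* pixel clips, i.e. the input cannot have come from
the model). The imaginary residue after the inverse transform is recorded
as `imag_rms_ratio` and is at machine-precision level on noiseless input.
Retrieved maps are estimates and may legitimately dip below zero under
noise or ringing; they are not clamped, which also keeps the
thickness/electron-density consistency identity exact.

**Working points.** `working_point()` inverts the illumination curve by
bisection to 1e-9 relative tolerance on a chosen monotone branch; the apex
(zero slope) is rejected, since a linearized working point without
refraction sensitivity cannot be used. Tabulated curves are interpolated
with a cubic spline, re-normalized to unit apex (warning beyond 5%
deviation), and never extrapolated.

## What the synthetic phantoms emulate — and what they do not

`phantom_cylinder_wire()` reproduces the chord profile of nominal-diameter
cylindrical wires: the quantitative accuracy benchmark. The
end-to-end recovery test simulates the mixed image with the *spatial*
linearized model and retrieves with the *spectral* filter, so it crosses
discretizations and padding — the recovered peaks are 499.6 µm (PET
500 µm nominal) and 198.4 µm (PEEK 200 µm nominal) on 256×64 grids.

`phantom_textured()` is a qualitative stand-in for a botanical sample
(flat membrane with cell-like low-thickness spots, plus pollen-grain-like
super-Gaussian blobs). Its default amplitudes (20 µm blobs over an 8 µm
membrane, 20 µm lateral scale at 1.6 µm sampling) keep the refraction beam
shift below half the illumination-curve width so the linearized forward
model remains valid. Real specimens differ in ways the phantom does not
capture: sub-resolution texture, violations of the constant-$\delta/\beta$
assumption across mixed materials, and detector effects other than
Poisson noise (gain variations, readout noise, flat-field structure).
Passing the phantom tests therefore demonstrates the *algorithm*, not
detector-grade robustness.

The noise study adds Poisson noise at 10 photons/pixel (relative standard
deviation $1/\sqrt{10} \approx 32\%$) to the textured-phantom image before
retrieval: the filtered retrieval's RMSE is ~60× below the pure
log-retrieval's on the same noisy input, and the three most prominent
structures remain above 3σ of their local object-free background (median
criterion — at this dose the weakest structures are genuinely marginal,
which is consistent with "most structures survive", not all).

## Streak suppression: scope of the claim

The acceptance property compares, at matched dose (one full-dose image
vs. two half-dose images), the streak index of the single-image retrieval
against the two-image + 1D-integration baseline on the wire bench at
$10^7$ photons/pixel — a typical 1 s synchrotron CCD exposure
(≈10¹⁰–10¹¹ ph mm⁻² s⁻¹ over a 46 × 20 µm pixel). There the ordering is
robust: single-image indices of 0.004–0.04 versus 0.26–0.40 for the
baseline over 20 seeds.

An honest limitation found while characterizing this comparison: the
ordering of the *normalized* streak index inverts at low dose
(≲10⁵ ph/pixel). The single-image filter passes $(\xi_y = 0,
\xi_x \text{ small})$ modes at unit gain — they are anchored only by the
weak attenuation signal — so its surviving low-frequency noise is itself
column-structured, even while its absolute RMSE remains competitive and
its advantage over the unfiltered log retrieval grows. The streak-index
ordering is therefore a statement about the high-dose regime of the wire
experiment, not about arbitrary photon budgets.

## Problem sizes

All shipped tests and the acceptance script run on desk-scale grids chosen
to resolve the physics: 256×64 for the wire bench (5.1 mm × 2.9 mm field),
192×192 for the petal-like bench (0.31 mm square), 256×256 for the
machine-precision inversion check, padded internally to powers of two.
The whole suite completes in well under a minute.

## Known limitations

* Monochromatic beams only; no polychromatic laboratory-source extension.
* The 1D edge model: no 2D aperture/mask geometry, no modelling of the
  step-and-shoot scan itself (images are emitted directly at the scan
  sampling).
* Near-field only: the TIE term replaces a Fresnel propagator.
* Objects with structure at the frame boundary are reconstructed with a
  smooth low-frequency bias (the boundary-information limit of a kernel
  longer than the field of view); errors stay smooth — no spikes — but
  full-frame gradients (a wedge spanning the image) are quantitatively
  degraded.
* No detector gain/readout noise, no flat-field artefacts, no CT.
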