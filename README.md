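# eiphase

Single-image phase retrieval for edge-illumination (EI) X-ray
phase-contrast imaging, in R.

EI setups convert X-ray refraction into intensity changes by partially
masking the beam with a misaligned aperture pair: the acquired image mixes
attenuation contrast, differential-phase (refraction) contrast along the
scan direction *y*, and near-field free-space-propagation contrast along
*x*. Classical EI processing separates these with **two** images taken in
different configurations, and turning the resulting refraction image into
a phase/thickness map requires a 1D integration that is notorious for
vertical streak artefacts. `eiphase` implements the single-image
alternative for quasi-homogeneous objects: under a constant δ/β
assumption the whole mixture collapses to one complex Fourier-domain
filter that never diverges, and one image yields the object thickness or
projected electron density directly.

It is aimed at synchrotron/laboratory XPCi practitioners and method
developers who want a reference implementation with a fully synthetic,
ground-truthed test bench: forward simulation, retrieval, the classical
two-image + integration baseline, and quantitative comparison metrics.

## The model in brief

For a homogeneous object of thickness `t(x,y)`, refractive index
`n = 1 − δ + iβ`, attenuation `μ = 2kβ` and transmission `T = exp(−μt)`,
the normalized signal at a working point `(C0, C1)` of the illumination
curve `C(y_e)` is

    S_n = [ T + z (C1/C0) T Δθ_y − (z/k) ∂x(T ∂xΦ) ] ⊛x LSF_x,

with `Φ = −kδt` and `Δθ_y = (1/k) ∂yΦ`. In Fourier space this is
`F{S_n} = D · F{exp(−μt)}` with

    D(ξx, ξy) = MTF_x(ξx) · [ 1 + A ξx² + i A (C1/C0) ξy ],
    A = zδ/μ = (z/2k)(δ/β),

so the retrieval is a single FFT division followed by a logarithm:

    t = −(1/μ) ln Re F⁻¹[ F{S_n} / D ].

`|D| ≥ MTF_x > 0` everywhere and `D(0,0) = 1`: a never-diverging low-pass
that suppresses noise at high frequencies while the attenuation signal
anchors the low ones. The projected electron density version replaces
`1/μ` by `1/γ`, `γ = 2kσ/(δ/β)`, `σ = r_e λ²/2π`, and needs only the δ/β
ratio.

## Worked example: recovering a wire diameter from one image

The bundled benchmark reproduces a synchrotron wire measurement: a 500 µm
PET wire imaged at 27 keV with 20 µm / 250 µm slit apertures, 3.85 m
propagation, 50% illumination, 20 µm scan steps and 46 µm pixels.

```r
library(eiphase)

pet <- ei_materials("PET")
pet
#> <ei_material> PET at 27 keV: delta = 4.09e-07, beta = 7.83e-11 (delta/beta = 5223)

curve <- wire_benchmark_curve()
working_point(curve, 0.5, "lower")
#> <ei_working_point> lower branch: y_e = 0 um, C = 0.5, C' = 0.05 /um

res <- wire_recovery_experiment(pet, 500)   # simulate, add nothing, retrieve
sprintf("retrieved peak: %.2f um (error %+.2f%%)", res$peak_um,
        100 * (res$peak_um - 500) / 500)
#> "retrieved peak: 499.58 um (error -0.08%)"

res$comparison
#> <ei_comparison> rmse = 2.6048, streak_index = 0, clipped_fraction = 0
```

The working point confirms the 50% illumination geometry (the lower edge
of the detector aperture sits exactly at the beam-profile centre, where
half the beam passes), and the retrieved vertical profile peaks within
0.1% of the nominal diameter; the 2.6 µm RMSE is dominated by ringing at
the wire's edge-on chord singularity. `res$profile` holds the
retrieved-vs-expected profile pair for plotting.

The same pipeline is scriptable from a shell:

```sh
exec/eiphase demo --out-dir ei_demo
#>  PET wire: nominal 500 um, retrieved peak 499.58 um (-0.08%)
#> PEEK wire: nominal 200 um, retrieved peak 198.42 um (-0.79%)
```

Other subcommands (`phantom`, `simulate`, `retrieve`, `baseline`,
`compare`) expose the full pipeline on 32-bit float TIFFs with sidecar
JSON metadata; every run writes its resolved configuration next to its
outputs and is byte-reproducible given the same seeds.

## Layout

- `R/` — materials and geometry, illumination curves, phantoms and noise,
  forward model, Fourier-filter retrieval, two-image baseline and
  metrics, TIFF/CSV I/O, CLI.
- `exec/eiphase` — command-line launcher.
- `inst/extdata/materials.csv` — tabulated optical constants (PET, PEEK
  at 27 keV; water at 9.7 keV).
- `tests/testthat/` — unit, property and acceptance tests (all synthetic;
  no external data).
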