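---
title: "Single-shot projected-thickness retrieval with polychromatic lab sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-shot projected-thickness retrieval with polychromatic lab sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasethick)
```

## The problem

Near-field propagation-based X-ray phase-contrast imaging recovers the
*projected thickness* `T(x, y)` of a single-material object from one
flat-corrected intensity image. For a homogeneous object with complex
refractive index `n = 1 - delta + i beta`, the Paganin operator inverts the
transport-of-intensity image formation with a single Fourier-space low-pass:

    T = -(1/mu) log F^-1 [ F(I / I_R) / (1 + pi lambda (gamma z/M - k s^2) |nu|^2) ]

with `mu = 4 pi beta / lambda`, `gamma = delta / beta`, `z` the
object-detector distance, `M = (SOD + ODD) / SOD` the cone-beam
magnification, `s` the source size, `k = 2 pi / lambda`, and `nu` the spatial
frequency on the object-plane grid in cycles per unit length. The package
implements this operator (`retrieve_pt()`) together with three relatives:

* `retrieve_at()` — the weak-absorption linearisation
  `T = (1/mu) F^-1[F(1 - I/I_R) / (...)]`; exact only as `mu T -> 0`, and a
  systematic underestimator for millimetric organic samples
  (`(1 - exp(-mu T))/mu < T`).
* `retrieve_st()` — the speckle-referenced variant: the same operator applied
  to the ratio of a sample+diffuser image and a diffuser-only reference.
* `retrieve_mpt()` — the two-material extension for a sample with known total
  thickness `A = T1 + T2`, which retrieves `T2` from contrast differences
  (`Delta mu`, `Delta gamma`) after factoring `exp(-mu_1 A)` out of the
  reference.

Laboratory microfocus sources are polychromatic, so `delta`, `beta`, `mu`,
`lambda` are not single numbers. Three strategies are provided through
`retrieve_polychromatic()`:

* **EA** — evaluate the material at the spectrum's mean energy;
* **PA** — average `delta` and `beta` themselves over the spectrum
  (Jensen's inequality makes these systematically larger than the EA values
  when the constants decrease with energy);
* **TA** — retrieve a thickness map at each of `n` energies spanning the
  spectrum and average the maps with the spectral weights.

All spectral averages use one definition (`average_over_spectrum()`): the
ratio of trapezoid-quadrature integrals of `Q(E) D(E)` and `D(E)` on the
stored grid, with single-bin spectra treated as discrete lines.

## Frequency convention and the source term

The filter's `nu` is spatial frequency in cycles/mm. With that reading,
`pi lambda (gamma z / M) |nu|^2` is dimensionless and reduces, for `s = 0`,
to the standard single-distance filter `1 + (lambda z gamma / 4 pi M) |q|^2`
written in angular frequency `q = 2 pi nu`; with angular frequency the
printed coefficient would be off by `(2 pi)^2`. The dimensional check lives
in `tie_multiplier()` and the eigen-mode test of the filter.

The source term `- k s^2 |nu|^2` is the first-order expansion of a Gaussian
blur `exp(-2 pi^2 sigma^2 |nu|^2)` with `sigma = s` on the object-plane
grid (`2 pi^2 s^2 = pi lambda k s^2`). The package therefore treats `s` as
the Gaussian-sigma penumbra width in object-plane coordinates: the Fresnel
simulator blurs with exactly that kernel, and the TIE simulator carries the
linearised term inside its multiplier so that forward and inverse filters
are matched by construction. Whether a vendor's quoted focal-spot number is
a sigma, FWHM or diameter is a calibration question outside the operator
itself.

## The forward simulator and its oracle property

`forward_polychromatic()` maps the cone beam to an equivalent parallel
geometry (effective distance `ODD/M`, object-plane pixel `p/M`) — the same
convention the retrieval filters use, so simulator and solver share one
geometry. Two modes:

* **TIE mode** applies, per energy, the Fourier multiplier
  `1 + pi lambda (gamma z/M - k s^2)|nu|^2` to the Beer-Lambert contact
  image. This is the exact forward counterpart of the retrieval filter.
  Because every filtered transform in the package mirror-pads the raster to
  twice its size (an even-symmetric extension that every even multiplier
  preserves) and crops afterwards, forward-then-inverse is the identity to
  machine precision — the central oracle of the test suite.
* **Fresnel mode** propagates the complex contact field with the paraxial
  angular-spectrum kernel and applies the Gaussian source blur. TIE and
  Fresnel images of a weak, slowly varying object agree to first order; the
  discrepancy shrinks quadratically with the object's amplitude (tested).

A diffuser screen multiplies the contact field of both the sample and the
reference image. In TIE mode each screen is filtered with *its own* `gamma`
and the two filtered intensities are multiplied — correct to first order
for two weak screens, and necessary because the sandpaper's `gamma` is an
order of magnitude below nylon's. Poisson noise is optional and seeded
(`photons` expected counts per pixel at unit intensity; the default study
uses 5e4, a typical CMOS flat-field exposure).

Polychromatic sums and TA retrieval resample the spectrum onto evenly
spaced energy nodes by *mass-conserving hat deposition*: each bin's
trapezoid mass is split linearly onto its two neighbouring nodes. This
preserves total weight and each emission line's mean energy exactly, so the
quadrature converges at the rate of the smooth per-energy images rather
than of the spiky spectral density. Point-sampling a line spectrum (width
0.25 keV) at 101 of 1500 grid points would otherwise mis-weight the lines
by tens of percent. Spectra with fewer bins than nodes are used exactly,
which keeps discrete-line algebra (mono- and two-line tests) bit-exact.

## Synthetic study conditions

The package carries a self-contained synthetic twin of a 50 kV microfocus
bench so every operator is testable without downloads:

* **Geometry** — SOD 600 mm; ODD 200/300/400 mm (M = 1.33/1.50/1.67);
  source size 0.02 mm; detector pixel 13.5 um. Projection approximation
  holds throughout (`fresnel_number()`: NF = 25 for the worst case of a
  1 cm object at 0.1 nm).
* **Phantoms** — three horizontal nylon fibers of 1.02/0.81/0.71 mm
  diameter (`three_fiber_phantom()`; chord profile
  `T(x) = d sqrt(1 - 4((x-x0)/d)^2)`), a 10 mm two-material plate whose
  pointwise sum is exactly the total thickness (`two_material_plate()`),
  and a stacked-sandpaper diffuser (`make_diffuser()`): three layers of
  clipped, smoothed Gaussian fields with correlation length ~18 um (P1000
  SiC grit) rescaled to one particle size mean thickness per layer. The
  fibers are constant along y so 100-row vertical averaging
  (`extract_profile()`) is meaningful. Fiber spacing is not constrained by
  any reference layout; the defaults at 0.25/0.52/0.78 of the field width
  simply keep the fibers disjoint.
* **Spectrum** — `make_synthetic_spectrum()` builds a *detected* spectrum
  stand-in: Kramers continuum `(kvp - E)/E`, tungsten L fluorescence lines
  (8.40/9.67/11.29 keV), 0.8 m air-path Beer-Lambert filtration, and a
  thin-scintillator absorption weight `1 - exp(-c (10/E)^3)`. A bare
  Kramers shape is nothing like what a scintillator-coupled CMOS detects
  and makes every polychromatic average pathological. The two free knobs
  (line fraction 0.3636, scintillator depth 0.5717) were calibrated once
  against the two bench observables the study fixes — detected mean energy
  10.3 keV, rising to 11.4 keV behind the three-layer SiC diffuser — and
  are not otherwise adjusted.
* **Materials** — `toy_material()` provides power-law stand-ins anchored at
  10.3 keV (nylon: delta 2.3e-6, beta 2.6e-9). `delta ~ E^-2` is exact far
  from edges. For beta the far-from-edge photoabsorption law `E^-4` is
  *wrong in band* for light organics: Compton absorption flattens the
  effective exponent to ~2 over 5-50 keV, and with `E^-4` a millimetre of
  nylon becomes ~50x too transparent above 30 keV, which makes per-energy
  thickness averaging diverge. The toy organics therefore use
  `beta ~ E^-2` (equivalently `mu ~ 1/E`), the in-band dependence the
  fiber-study literature itself quotes; SiC, still photoelectric-dominated
  in band, uses `beta ~ E^-4`. The diffuser roughness default (0.55
  relative fluctuation per layer) is calibrated so the simulated 3-layer
  screen shows ~12% speckle visibility, the bench's quoted value.

## What the twin shows — and what it cannot

With these conditions the package's `run_experiment()` reproduces the
qualitative structure of the polychromatic fiber study: AT underestimates
strongly once `mu T` is of order one; PA's inflated `mu` makes it the worst
strategy; support-width estimates `d_x` are nearly technique-independent
while apex estimates `d_T` are not; diameter *ratios* are far more robust
than absolute diameters; and the speckle-referenced maps are noisier than
the plain ones at matched conditions.

One quantitative limit deserves emphasis. For any smooth in-band `mu(E)`,
every strategy's thin-object bias is controlled by the spectral width: with
`mu ~ 1/E` the recovered-to-true ratio at the apex is approximately
`<E><1/E>` (about 1.08-1.10 for any detected spectrum consistent with both
calibration means above, because the diffuser-hardening shift of +1.1 keV
cannot be produced by a narrow spectrum). The twin therefore shows
systematic apex-diameter overestimates of several percent for *all*
strategies — larger than the best experimental figures reported for real
detector data, whose exact spectral shape is not recoverable from printed
summary numbers. The acceptance script computes these quantities from
scratch rather than asserting them; the ratio-based metrics, which cancel
the common multiplicative bias, are the robust quantitative output of the
twin. Equally, with `beta ~ E^-2` exactly, the TA and EA strategies become
nearly degenerate at the profile apex (`<1/mu>` is then linear in `E`, so
thickness averaging reduces to mean-energy compensation); their ranking on
the twin is a near-tie decided by fit-level detail rather than by the
mechanism that separates them on real materials, whose beta curvature
deviates from a single power law.

## Numerical choices

* Denominator guard `eps = 1e-6` with a clamped-frequency count (negative
  denominators are possible when `k s^2 > gamma z / M` at high frequency);
  log arguments clamped at 1e-12 with a clamped-pixel count. Both counts
  ride on the result as attributes and go into CLI provenance JSON.
* Mirror padding to 2x before every filtered transform; wraparound
  artefacts stay outside the cropped frame and matched filter pairs compose
  exactly.
* TA sample count: the reference analysis uses 1500 evenly spaced energies;
  with hat-deposited weights the default 101 changes recovered fiber maps
  by well under 1e-3 mm (the convergence test in the suite tracks
  successive refinements). The experiment driver keeps 101 for a ~5-minute
  nine-cell study at 512^2.
* Fiber fits (`fit_fiber()`): Levenberg-Marquardt on
  `dT sqrt(1 - 4((x - x0)/dx)^2)` with x0 at the profile argmax, dT at the
  maximum, dx from the width above 10% of the maximum; bounds keep all
  parameters positive and below twice the window width. Background points
  stay in the residual — they identify `dx`.
* Thickness maps are written as 32-bit float TIFF scaled to [0, 1] with the
  scale factor in a JSON sidecar (together with pixel size, units, material
  and caller-supplied provenance), which round-trips to single precision.

## Limitations

* The diffuser is placed in the object plane; its true plane (closer to the
  source) would add a small geometric rescaling of the speckle.
* No detector point-spread function, no scatter, no partial coherence
  beyond the Gaussian source kernel.
* The toy materials are labelled stand-ins; quantitative work on measured
  images requires tabulated optical constants
  (`read_material_table()`).
* The two-material operator takes the total thickness `A` as known input,
  as the plate geometry provides; it does not estimate `A`.
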