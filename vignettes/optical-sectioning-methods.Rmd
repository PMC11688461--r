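---
title: "Comparing optical-sectioning methods: models, simulator and metrics"
author: "optisect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing optical-sectioning methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(optisect)
```

Optical sectioning is the rejection of out-of-focus fluorescence so that a
single focal plane can be imaged from a thick, densely labelled sample.
Confocal pinholes, nonlinear (two-photon) excitation, structured and hybrid
illumination, light sheets and off-axis line-scan detection all achieve it
by different physical constraints, and their performance trade-offs —
sectioning strength, resolution, speed, SNR, penetration, phototoxicity —
are usually argued qualitatively.  This package puts the methods on one
quantitative footing: a common defocused optical transfer function (OTF)
drives every axial-response formula, an image-formation simulator
reproduces the off-axis multiplexed line-scan acquisition digitally, and a
set of closed-form calculators covers the remaining metrics.  This
vignette records the models, the parameter choices, the numerical
decisions, and the limits of what the synthetic studies can show.

## Normalized coordinates and the defocused OTF

All axial-response integrals are evaluated in dimensionless optical
coordinates.  The lateral spatial frequency `s` is normalized so that the
incoherent cutoff of the detection objective is 2 (physical frequency
times lambda/NA).  The defocus coordinate is the high-aperture form

    u = (8 pi n z / lambda) sin^2(alpha/2),   sin(alpha) = NA / n,

applied per arm: excitation wavelength and illumination NA for the
illumination arm, emission wavelength and detection NA for the detection
arm (`opticalCoordinate()`).  The reference configuration throughout is a
water-immersion 20x / NA 1.0 objective (n = 1.33) imaging a green
fluorophore (0.488 um excitation, 0.520 um emission).  With it, 1 um of
physical defocus is about 11 normalized units on the detection arm.  The
u-to-micrometre conversion is a convention of this package: the
dimensionless formulation is what makes the cross-method comparisons
well-posed, and only shapes and orderings — never absolute micrometre
widths of the normalized curves — are asserted by the test suite.

The defocused OTF is the normalized autocorrelation of the pupil with a
quadratic defocus phase,

    T(s, u) = (4/pi) Int_0^{1-s/2} cos(u s x) sqrt(1 - (x + s/2)^2) dx,

with the classical closed form at u = 0 kept as a regression anchor.  The
square-root endpoint is removed by the substitution x + s/2 = cos(theta),
after which composite Simpson quadrature converges to ~1e-12; the test
suite cross-checks values against a brute-force 2D autocorrelation of the
complex defocused pupil.  `makeOTFGrid()` samples 513 frequencies on
[0, 2] and 401 defocus values on [-40, 40] by default (computing u >= 0
and mirroring, since T is even in u); halving the grid changes every
reported FWHM by less than 0.5%, which the suite asserts.

## Axial responses and sectioning strength

Each method's response I(u) of a thin fluorescent sheet is an integral of
the OTF against method-specific apodizations, normalized to I(0) = 1, with
the sectioning strength reported as the FWHM (linear interpolation between
the bracketing grid points on each side of the peak):

* **Confocal pinhole** `Int jinc(b s) T^2(s,u) jinc(beta s) s ds` — b is
  the illumination-spot radius, beta the pinhole radius, both in
  normalized units; jinc(x) = 2 J1(x)/x equals 1 at the origin.
* **Confocal slit / line confocal** — the 1D analogue with
  snc(x) = sin(x)/x factors.
* **Two-photon** `Int jinc(2 b s) T^2(s, u/2) s ds` — the squared
  excitation doubles the spot argument and halves the defocus argument.
  An optional detection pinhole constrains the detection arm, multiplying
  the integrand by jinc(beta s) T(s, u).  A bare jinc(beta s) apodization
  (no detection transfer) would mathematically *widen* the response by
  down-weighting high frequencies, contradicting the physical behaviour of
  a pinhole, so the constrained-arm form is used.
* **Structured illumination** — the demodulated single-frequency response
  |T(s0, u)| (first power: the demodulation takes a root of the squared
  band integral).
* **Hybrid illumination** `sqrt(Int_{smin}^{smax} T^2(s,u) T(s,0) ds)` —
  a filter band in the demodulation.
* **Light sheet** `exp(-u^2 / 2 c^2)` — the sheet confines excitation;
  on the detection axis T(0,0,u) = 1.
* **LiMo** `Int snc(b s) T^2(s,u) snc(beta s) [1 - cos(2 beta s)] ds` —
  the linear decoding of off-axis line detection; the 1 - cos factor is
  what removes the slowly decaying low-frequency content that limits the
  plain slit.

Default parameters for cross-method comparisons: ideal illumination
(b = 0), pinhole/slit radius beta = 0.5 (about one camera-pixel half-width
back-projected), structured frequency s0 = 1, hybrid band [1, 2], and the
light-sheet parameter c taken as the normalized defocus of the Rayleigh
range z_R = n lambda_ex / (pi NA_ill^2) of the illumination objective
(`lightSheetC()`; c ≈ 2.4 for NA 1.0).  All are configurable; the
defaults are the single points at which the families of curves are
collapsed into one ranking.

Two behaviours worth recording.  First, the structured-illumination
optimum sits at s0 = 1, half the cutoff, and the hybrid band [1, 2]
centred on that optimum beats both the full band and narrow bands pushed
against the cutoff: frequencies near s = 2 have almost no pupil overlap
and *decay slowly* with defocus, so "narrower filter" does not mean
"stronger sectioning" monotonically.  Second, `sectioningRanking()`
evaluates two-photon with the comparison integrand
`Int T(s/2, u/2) T(s,u) s ds`, which keeps the (doubled-wavelength)
illumination and the unconstrained detection as separate transfer factors;
the squared excitation-only form `T^2(s, u/2)` describes the excitation
confinement alone and is wider than the line-confocal response, while the
comparison form ranks two-photon between hybrid illumination and the line
confocal, the ordering the ranking asserts:

light sheet < LiMo < confocal < structured < hybrid < two-photon < line confocal.

## Deep-background tails

Sectioning strength near focus does not determine how a method handles the
*accumulated* background of a thick sample.  For that the package
integrates the defocused response from a lower bound u1 to (numerically)
infinity, using the paraxial kernel [J1(u s)/(u s)]^2 throughout
(`tailIntegral()`).  The substitution xi = u s reduces every branch to
cumulative Bessel integrals, tabulated once on a dense grid:

| branch         | I(u)                                   | tail order        |
|----------------|----------------------------------------|-------------------|
| natural (LiMo) | u^-3 Int_0^{2u} J1^2 d xi              | ln(u1) / u1^2     |
| confocal       | u^-2 Int_0^{2u} J1^2/xi d xi           | 1 / u1            |
| two-photon     | 4 u^-2 Int_0^{u} J1^2/xi d xi          | 1 / u1            |
| structured     | &#124;2 J1(u s0)/(u s0)&#124;          | 1 / sqrt(u1)      |
| light sheet    | exp(-u^2 / 2 c^2)                      | super-polynomial  |
| line confocal  | u^-1 Int_0^{2u} (J1/xi)^2 d xi         | divergent (log)   |

Two deliberate choices.  The structured branch uses the *magnitude* of
the demodulated response, not its square: the demodulation applies a
square root, and only the first-power kernel produces the 1/sqrt(u1)
order (the squared kernel decays as 1/u1^2).  And the kernels keep their
natural prefactors rather than being renormalized to I(0) = 1; this is
the convention under which the ranking of the integrated background at
u1 = 2 (natural < confocal < two-photon < structured < line-confocal)
holds, and the fitted log–log orders are prefactor-independent anyway.
"Infinity" means a truncation bound of 1e4 with a convergence check for
the convergent branches; the line-confocal integral grows by a constant
amount per decade of the bound and is only ever reported as a growth
profile (`divergenceCheck()`), never as a number.  Fixed-grid Simpson and
piecewise-adaptive quadrature agree to 0.5%.

## The PSF engine

The simulator needs x-projected profiles: the line-illumination intensity
L(x, z) (the y-integral of the defocused point PSF) and the y-projected
detection profile P(x, z).  Both are computed by FFT over pupil chords:
for each chord rho_y = const, the partial field is the 1D Fourier
transform of chord(rho_x) exp(i u rho^2 / 2), and the projection is the
incoherent sum over chords.  Discrete Parseval then makes the
x-integrated energy *exactly* independent of defocus — the conservation
law the tests assert at machine precision — and the field is fully
resolved on the FFT grid, avoiding the ring-aliasing that a sampled-Airy
route suffers at 0.03 um steps.  Radial point PSFs (for the point-source
and lateral-resolution work) use dense J0 pupil quadrature instead.

Sub-detector PSFs integrate P over pixel strips at off-axis offsets
(n - (n_lines+1)/2) * pitch, via a trapezoidal cumulative with
interpolated fractional endpoints; this keeps mirrored strips exactly
symmetric (a half-sample Riemann offset here visibly imbalances the two
central lines) and makes the strips tile the full aperture exactly, so
the sum of sub-PSFs reproduces a single full-aperture detector to
rounding error — the conservation identity linking off-axis separated
detection to coaxial wide-field detection.

`maskEquivalence()` demonstrates the scanning-system identity that
patterning the illumination equals masking the detector: with matched
arms (emission wavelength set to the excitation value, same objective)
and a raised-cosine pattern, the patterned-illumination kernel
(M * L)(x, z) P(x, z) and the strip-synthesized detection-mask kernel
L(x, z) (M * P)(x, z) image a random phantom identically to better than
1%, the residual being the strip discretization of the mask.  The
identity genuinely requires matched point-spread functions; with
different excitation/emission wavelengths it holds only approximately.

Lateral resolution uses two effective-PSF modes: *wide* (the diffraction
PSF) and *focused* (its square, both arms constrained).  The Gaussian
approximation reproduces the exact sqrt(2) = 1.41 confocal resolution
gain; the Airy model gives 1.39.  `resolutionRanking()` maps methods to
modes (confocal/spinning disk: focused; LiMo/LC: the x/y average of
focused and wide; light sheet: wide; two-photon: focused at the doubled
excitation wavelength).  HiLo and SIM are wide-field-detection methods
whose diffraction PSFs tie with the light sheet's, yet their
reconstructions retain low-pass content that broadens the effective PSF;
this is encoded as small configurable broadening factors (1.05 and 1.10).
Those factors are this package's own device for ordering within the
wide-field group — the diffraction model alone cannot separate them — and
the absolute FWHMs of the other methods do not depend on them.

## The scan simulator

Stage scanning makes the acquisition shift-invariant along the scan axis,
so each off-axis image I_n is, exactly, a depth sum of the sample slices
convolved with the product kernel K_n(x, dz) = L(x, dz) D_n(x, dz) — the
"rearrangement" of spatiotemporally multiplexed columns into per-offset
images is implicit in this formulation.  Two modelling simplifications:
the defocused detection blur along the line direction y is applied as a
separable normalized profile per depth (the true 2D detection PSF is not
x/y separable; the separable form preserves the energy and the scale of
the blur, which is what the background statistics depend on), and the
volume is zero-padded by the kernel support, so structures outside the
simulated block contribute nothing.  Kernels are evaluated on an 11-fold
sub-voxel grid and box-averaged into voxel bins, matching what a detector
pixel integrates; the scan step must equal the lateral voxel size.

Noise is applied last: Poisson shot noise on expected photoelectrons plus
Gaussian read noise (sigma = 2 e-).  The photon budget is specified as
the expected count at the brightest in-focus pixel (default 2000 e-),
i.e. exposure is normalized to the sample, the way a practitioner sets
laser power to fill the camera's usable well depth.  The published
simulation protocol states no noise settings; these defaults are a
mid-range sCMOS operating point, and the reconstruction ordering below is
stable from roughly 1000 to 4000 e- (at a few hundred photoelectrons the
rectified shot noise starts to dominate the difference-based DSIM
background, as it would on a real instrument).

## Phantoms

`trajectoryVolume()` rasterizes smoothed random-walk trajectories as
tubes: per-step direction jitter (sd 0.25) bounds the curvature, the tube
radius is 0.5 um, and the intensity follows a lognormal drift along the
path (fluorophore density varying with axial position).  The desk-scale
default is 256 x 256 x 128 voxels at 0.325 um lateral / 0.5 um axial
sampling with 48 paths of 1200 steps (~3% labelled voxels) — filament
density comparable to a densely labelled neurite field; the full-scale
1024^3 block at the same voxel sizes is a configuration, not a test
requirement.  An optional uniform background density emulates diffuse
tissue fluorescence (default 0).  Analytic probes — `fluorescentSheet()`
and `pointSource()` — validate the simulator against the axial-response
and PSF modules: a swept sheet traces the axial response, a centred point
reproduces the kernel section.

What the phantom does *not* emulate matters for interpretation: no
scattering, no aberrations, no stage jitter, no photobleaching, no
somata/vasculature morphology.  Passing the synthetic studies shows the
*algorithms* behave as the theory predicts under ideal image formation;
it does not certify performance in scattering tissue, where light-sheet
and modulation contrasts degrade in ways the model excludes.

## Reconstructions and SBR

With six lines (3 and 4 straddling the illumination line):

* `LC = I3` — the virtual-slit line-confocal image;
* `DSIM = sqrt(5) |I3 - I1|` (simplified) or the three-phase combination
  |sum_i P_i exp(2 pi i j/3)| with phase masks (1,4), (2,5), (3,6); on
  symmetric in-focus stacks the two agree in shape to ~5% after scale
  normalization, and the sqrt(5) / mask constants are exposed rather than
  derived;
* `DHiLo = I3 - gamma LP(I3)` with gamma = 0.9 and a Gaussian low-pass,
  plus a general HP + eta LP(C_s I3) path with the local contrast
  C_s = smoothed (I3 - I1)/(I3 + I1);
* `LiMo = 2 (I3 + I4) - (I1 + I2 + I5 + I6)` — the unsimplified
  combination is canonical (it needs no free constant).

Negative values are clipped at zero for display and metrics; pre-clip
images are retained so linearity can be tested.  The DHiLo low-pass
cutoff defaults to 0.2 cycles/um (about a 5 um wavelength).  This is a
deliberate departure from a "quarter of the sampling frequency" rule: at
0.325 um pixels that rule puts the cutoff *above* the frequency content
of the filament images themselves, so the "low-pass" would capture the
fibres and the subtraction would remove signal rather than haze.  The
HiLo decomposition is only meaningful when the low-pass models the
defocused background, which is laterally smooth on the multi-micrometre
scale; 0.2 cycles/um sits between the haze (below ~0.1) and the fibres
(above ~0.5).

SBR is the mean over a signal mask divided by the mean over a background
mask; `sbrMasks()` derives both from the phantom's labels (structure
within 1 um of the focal plane, dilated by 1 px, vs pixels at least 6 px
from any in-focus structure).  On the default seeded phantom the ordering
is LiMo > DHiLo > DSIM > LC, stable across seeds — LiMo cancels the
multi-line background exactly up to the depth-of-focus residual, DHiLo
removes only the smooth part and keeps high-frequency background plus a
(1 - gamma) remnant, DSIM's rectified difference pays a noise floor, and
LC keeps the background wholesale.  The acceptance suite asserts exactly
this ordering across three seeds at the full desk-scale size.

## Performance calculators

Imaging time: mosaic scanning `T_m = (t_m + sqrt(4M/a)) L^2/M^2 -
sqrt(4M/a)` (stop-and-stare tiling with triangular stage moves) and strip
scanning `T_s = L^2 t_s/(p M) + (L/M - 1) sqrt(4M/a)`.  With the
reference stage (M = 0.67 mm, a = 200 mm/s^2) the quadratic coefficients
are 1.45 s/mm^2 for point scanning (t_m = 2048^2 pixels at a
512^2 @ 30 fps scan rate = 533 ms), 0.28 for spinning disk (10 ms) and
0.276 for wide-field (8.3 ms), constant -0.12 s; small areas are
scanner-limited at t_m/M^2 (1.2 s/mm^2 for point scanning).  The
wide-field coefficient prints as 0.28 at two decimals; the commonly
quoted 0.27 is a truncation of the same arithmetic.

SNR: per-method single-image ratios in which apertures pay sqrt(S/S0),
and the off-axis reconstructions pay or gain through their modulation
combinations C_LiMo, C_SIM, C_HiLo.  The shared modulation profile
defaults to m = (0.5, 0.7, 1, 1, 0.7, 0.5) — all six lines retaining
appreciable modulation, as they do within the depth of focus — with
pinhole S/S0 = 0.25 and slit S/S0 = 0.5; under these conditions the
ordering is HiLo > LiMo > two-photon = light sheet > SIM > LC > confocal.
The profile is a declared study condition: a strongly peaked profile
(outer lines dark) raises C_LiMo and the HiLo contrast penalty together,
and can swap the HiLo/LiMo pair.

Penetration depth follows exp(-z/ls) for linear and exp(-2z/ls) for
nonlinear excitation (returned relative to the surface); phototoxic dose
is G = P t / S_area, and `scanningInvariance()` checks the defocus
invariance that makes scanning illumination spread dose evenly in depth.

## Problem sizes and runtime choices

The test and acceptance studies run at desk scale: OTF grids of 513 x 401
(unit tests mostly 257 x 201), simulator geometries of 48-64 pixel fields
with 32-33 planes for unit tests, and the full 256 x 256 x 128 phantom
with a 4096-point PSF grid for the three-seed reconstruction study.
These sizes resolve every asserted FWHM to better than 0.5% and keep the
whole suite in the low minutes on one core.  Session-level caching keyed
on the geometry makes the OTF grid, Bessel tables and scan kernels
one-time costs.

## Known limitations

* The paraxial tail kernels and the high-aperture OTF are different
  approximation regimes; the package keeps them separate (tails are an
  asymptotic analysis, responses a diffraction calculation) and never
  mixes them in one quantity.
* The u-to-micrometre mapping is a convention; absolute micrometre FWHMs
  of normalized curves are not claims.
* The simulator's separable y-blur and noiseless optics idealize the
  acquisition; scattering, aberrations and pattern instability are out of
  scope.
* Resolution ordering within the wide-field-detection group rests on
  declared broadening factors, not on a diffraction calculation.
* DSIM's sqrt(5) constant and phase masks are conventions exposed as
  parameters; only the shape equivalence of the two DSIM forms is
  asserted, on symmetric inputs.
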