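# optisect

Quantitative comparison of optical-sectioning fluorescence microscopy
methods in R.

Thick, densely labelled samples flood a microscope with out-of-focus
fluorescence; every optical-sectioning method — confocal pinholes and
slits, two-photon excitation, structured (SIM) and hybrid (HiLo)
illumination, light sheets, and off-axis line-scan detection with its
digital reconstructions (LC, DSIM, DHiLo, LiMo) — rejects that background
by a different physical constraint.  `optisect` puts them on one footing
for microscopists and methods developers choosing or modelling a
sectioning scheme:

* **A common OTF model.**  The defocused optical transfer function
  T(s, u) — the pupil autocorrelation with quadratic defocus phase, on
  normalized frequency s ∈ [0, 2] and defocus u — drives every method's
  axial response to a thin fluorescent sheet, e.g.

  I<sub>conf</sub>(u) = ∫ jinc(bs) T²(s,u) jinc(βs) s ds,
  I<sub>LiMo</sub>(u) = ∫ snc(bs) T²(s,u) snc(βs) [1 − cos 2βs] ds,
  I<sub>LS</sub>(u) = exp(−u²/2c²),

  with sectioning strength reported as the FWHM of I(u).
* **Deep-background asymptotics.**  Tail integrals ∫<sub>u₁</sub>^∞ I(u) du
  with the paraxial kernel [J₁(us)/us]², their fitted decay orders
  (1/u₁ for confocal and two-photon, 1/√u₁ for SIM, ln u₁/u₁² for LiMo,
  a divergent logarithm for the line confocal), and the resulting
  thick-sample ranking.
* **An image-formation simulator.**  Off-axis spatiotemporal-multiplexed
  line scanning: a synthetic 3D filament phantom is swept through a line
  focus, a six-line detector subarray records one image I₁…I₆ per
  off-axis position, and the four reconstructions
  LC = I₃, DSIM = √5·|I₃−I₁|, DHiLo = I₃ − γ·LP(I₃),
  LiMo = 2(I₃+I₄) − (I₁+I₂+I₅+I₆)
  are scored by signal-to-background ratio (SBR).
* **Performance calculators** for mosaic/strip imaging time, per-method
  SNR, penetration depth and phototoxic dose.

## Worked example

Rank the methods by sectioning strength under the reference system (20×,
NA 1.0 water immersion, 0.488/0.520 µm), then run the full synthetic
reconstruction study:

```r
library(optisect)

g <- makeOTFGrid()                      # defocused OTF, 513 x 401 grid
sectioningRanking(g, opticalConfig())
#>          method      fwhm
#> 1   light_sheet  5.677578
#> 2          limo  7.707456
#> 3      confocal  8.531286
#> 4    structured  9.131866
#> 5        hybrid  9.613200
#> 6    two_photon 10.599834
#> 7 line_confocal 12.172591
```

The `fwhm` column is the width of each method's axial response in
normalized defocus units (≈ 11 units per µm here): the NA 1.0 light sheet
sections most tightly, LiMo beats the confocal pinhole, and the plain
line confocal — whose accumulated background actually diverges with
sample thickness — is last.

```r
res <- runPipeline(runConfig(seed = 1))   # 256 x 256 x 128 filament phantom
res$summary
#>   method       sbr
#> 1     LC  6.875059
#> 2   DSIM 14.182063
#> 3  DHiLo 16.794846
#> 4   LiMo 34.047966
```

SBR is the mean reconstructed intensity over in-focus filament pixels
divided by the mean over structure-free background: the raw virtual-slit
image (LC) keeps the defocused haze, the difference-based DSIM and the
high-pass DHiLo suppress most of it, and LiMo's six-line linear
cancellation leaves only the depth-of-focus residual — the ordering
LiMo > DHiLo > DSIM > LC is stable across seeds.

Timing, SNR, resolution, depth and dose calculators are plain functions:

```r
mosaicCoefficients(t_m = 2048^2 / (512^2 * 30), M = 0.67, a = 200)
#> quadratic 1.45 s/mm^2, constant -0.12 s
snrRanking()          # HiLo > LiMo > TP = light sheet > SIM > LC > confocal
resolutionRanking()   # confocal best; two-photon last (doubled wavelength)
```

A command-line front end over the same functions lives at
`inst/scripts/optisect.R`
(`Rscript optisect.R curves|tails|simulate|reconstruct|metrics|run`), and
the methods vignette (`vignettes/optical-sectioning-methods.Rmd`)
documents the models, parameter defaults and numerical choices.

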