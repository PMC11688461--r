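# Shared fixtures.  Heavy deterministic objects (OTF grids, scan kernels)
# are cached inside the package session cache, so these helpers are cheap
# after their first call from any test file.

refOtf <- function() makeOTFGrid()

midOtf <- function() makeOTFGrid(s_points = 257, u_max = 40, u_points = 201)

testCfg <- function() opticalConfig()

testScan <- function(...) scanConfig(noise = "none", ...)

# small simulator geometry used across simulator/reconstruction tests
testKernels <- function() {
  scanKernels(testCfg(), testScan(), c(0.325, 0.325, 0.5), nz = 33,
              nfft = 2048, nchord = 128)
}

testZ <- function() seq(-5, 5, by = 0.5)

# brute-force defocused-OTF oracle: raw autocorrelation of the complex
# defocused pupil on an n x n Cartesian grid (independent of the package's
# 1D cosine reduction)
bruteOtf <- function(s, u, n = 512) {
  ax <- seq(-1 - s / 2, 1 + s / 2, length.out = n)
  g <- expand.grid(x = ax, y = ax)
  p1 <- complex(modulus = ((g$x + s / 2)^2 + g$y^2) <= 1,
                argument = u * ((g$x + s / 2)^2 + g$y^2) / 2)
  p2 <- complex(modulus = ((g$x - s / 2)^2 + g$y^2) <= 1,
                argument = u * ((g$x - s / 2)^2 + g$y^2) / 2)
  num <- sum(p1 * Conj(p2))
  den <- sum(Mod(p1)^2)
  Re(num / den)
}

# simple FWHM on a sampled profile (nearest-crossing, no interpolation)
fwhm1d_test <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  r <- pk + which(y[pk:length(y)] < half)[1] - 1
  l <- pk - which(y[pk:1] < half)[1] + 1
  x[r] - x[l]
}
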