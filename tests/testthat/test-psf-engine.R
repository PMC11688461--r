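test_that("line PSF is symmetric, peaked on axis, and broadens with defocus", {
  psf <- buildLinePsf(testCfg(), z = testZ(), nfft = 2048, nchord = 128)
  V <- psf@values
  i0 <- which.min(abs(psf@x))
  j0 <- which.min(abs(psf@z))
  expect_equal(which.max(V[, j0]), i0)          # in-focus peak at x = 0
  expect_equal(max(V[, j0]), 1)                 # normalized
  # symmetric in x about the line centre
  win <- (i0 - 400):(i0 + 400)
  expect_equal(V[win, j0], rev(V[win, j0]), tolerance = 1e-9)
  # x-profile FWHM grows monotonically with |z|
  fw <- vapply(seq_along(psf@z), function(j) fwhm1d_test(psf@x, V[, j]),
               numeric(1))
  pos <- psf@z >= 0
  expect_true(all(diff(fw[pos]) > 0))
})

test_that("energy is conserved across defocus", {
  pr <- projectedPsf(testCfg(), testZ(), "illumination", nfft = 2048,
                     nchord = 128)
  en <- attr(pr$values, "energy")
  expect_lt(diff(range(en)) / mean(en), 1e-12)
})

test_that("in-focus line profile matches a fine-grid pupil-integral oracle", {
  psf <- buildLinePsf(testCfg(), z = c(-1, 0, 1), nfft = 2048, nchord = 128)
  # brute force: radial point PSF from dense J0 quadrature of the pupil
  # integral, then numerically projected along the line direction
  cfg <- testCfg()
  lam <- wavelengthEx(cfg); na <- illuminationNA(cfg)
  r <- seq(0, 8, by = 0.005)
  rho <- seq(0, 1, length.out = 3000)
  J0M <- besselJ(outer(2 * pi * na * r / lam, rho), 0)
  amp <- J0M %*% (rho / length(rho))
  h <- as.vector(Mod(amp)^2)
  tt <- seq(0, 8, by = 0.005)
  xs <- seq(0, 1.0, by = 0.0325)
  prof <- vapply(xs, function(x0) {
    rr <- sqrt(x0^2 + tt^2)
    2 * sum(approx(r, h, rr, yleft = h[1], yright = 0)$y) * 0.005
  }, numeric(1))
  prof <- prof / prof[1]
  j0 <- which.min(abs(psf@z))
  i0 <- which.min(abs(psf@x))
  got <- psf@values[i0 + round(xs / (psf@x[2] - psf@x[1])), j0]
  expect_equal(got, prof, tolerance = 0.02)
})

test_that("sub-detector PSFs mirror and sum to the full aperture", {
  sub <- buildSubPsfs(testCfg(), testZ(), nfft = 2048, nchord = 128)
  # centred (n = 0-adjacent) lines have the largest in-focus peak
  j0 <- which.min(abs(sub@z))
  i0 <- which.min(abs(sub@x))
  on_axis <- sub@psfs[i0, j0, ]   # in-focus response at the line centre
  expect_true(all(on_axis[c(3, 4)] > on_axis[c(2, 5)]))
  expect_true(all(on_axis[c(2, 5)] > on_axis[c(1, 6)]))
  # mirror symmetry: sub-PSF(+n) equals sub-PSF(-n) reflected in x
  i0 <- which.min(abs(sub@x))
  win <- (i0 - 500):(i0 + 500)
  for (pair in list(c(1, 6), c(2, 5), c(3, 4))) {
    expect_equal(sub@psfs[win, j0, pair[1]],
                 rev(sub@psfs[win, j0, pair[2]]), tolerance = 1e-9)
  }
  # conservation: sum of strips equals the independently integrated full
  # aperture within 1% everywhere
  full <- fullAperturePsf(testCfg(), testZ(), width = 6 * sub@pitch,
                          nfft = 2048, nchord = 128)
  expect_lt(max(abs(subPsfSum(sub) / 6 - full)) / max(full), 0.01)
  expect_error(buildSubPsfs(testCfg(), testZ(), pitch = 1e-4), "grid step")
})

test_that("focused mode narrows the lateral PSF as expected", {
  cfg <- testCfg()
  expect_equal(lateralFwhm("wide", cfg, model = "gaussian") /
                 lateralFwhm("focused", cfg, model = "gaussian"),
               sqrt(2), tolerance = 1e-9)
  ratio <- lateralFwhm("wide", cfg, model = "airy") /
    lateralFwhm("focused", cfg, model = "airy")
  expect_gt(ratio, 1.3); expect_lt(ratio, 1.45)
  expect_lt(lateralFwhm("focused", cfg), lateralFwhm("wide", cfg))
})

test_that("resolution ranking reproduces the reference order", {
  rk <- resolutionRanking(testCfg())
  expect_identical(rk$method,
                   c("confocal", "spinning_disk", "limo", "line_confocal",
                     "light_sheet", "hilo", "sim", "two_photon"))
  # two-photon is below every one-photon focused method
  tp <- rk$fwhm_um[rk$method == "two_photon"]
  expect_gt(tp, rk$fwhm_um[rk$method == "confocal"])
  expect_gt(tp, rk$fwhm_um[rk$method == "light_sheet"])
})

test_that("illumination patterning equals a detection-side mask", {
  me <- maskEquivalence(testCfg())
  expect_lt(me$max_rel_dev, 0.01)
})
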