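test_that("all axial responses are normalized and decay", {
  g <- midOtf()
  params <- list(
    methodParams("confocal_pinhole", beta = 0.5),
    methodParams("confocal_slit", beta = 0.5),
    methodParams("two_photon"),
    methodParams("structured", s0 = 1),
    methodParams("hybrid", s_min = 1, s_max = 2),
    methodParams("light_sheet", c = 2),
    methodParams("limo", beta = 0.5))
  for (p in params) {
    cur <- axialResponse(p, g)
    I <- cur@intensity
    i0 <- which.min(abs(cur@u))
    expect_equal(I[i0], 1, tolerance = 1e-9, label = p@method)
    expect_true(all(I >= -1e-12), label = p@method)
    expect_lt(I[1], 0.25)                     # small at the grid edge
    expect_lt(I[length(I)], 0.25)
    expect_true(is.finite(fwhm(cur)), label = p@method)
  }
})

test_that("pinhole size controls confocal sectioning monotonically", {
  g <- midOtf()
  fw <- vapply(c(0.2, 0.5, 1, 2), function(beta)
    fwhm(axialResponse(methodParams("confocal_pinhole", beta = beta), g)),
    numeric(1))
  expect_true(all(diff(fw) >= 0))
  expect_lt(fw[1], fw[3])   # beta = 0.2 sections better than beta = 1
})

test_that("pinholes section better than slits of equal radius", {
  g <- midOtf()
  expect_lt(fwhm(axialResponse(methodParams("confocal_pinhole", beta = 0.5), g)),
            fwhm(axialResponse(methodParams("confocal_slit", beta = 0.5), g)))
})

test_that("two-photon: detection pinhole tightens, ideal confocal is tighter", {
  g <- midOtf()
  tp <- responseTwoPhoton(methodParams("two_photon"), g)
  tp_ph <- responseTwoPhoton(methodParams("two_photon"), g,
                             pinhole_beta = 0.5)
  tp_ph_small <- responseTwoPhoton(methodParams("two_photon"), g,
                                   pinhole_beta = 0.2)
  expect_lte(fwhm(tp_ph), fwhm(tp))
  expect_lte(fwhm(tp_ph_small), fwhm(tp_ph))
  ideal_conf <- axialResponse(methodParams("confocal_pinhole", beta = 1e-6), g)
  expect_gt(fwhm(tp), fwhm(ideal_conf))
})

test_that("structured illumination response is the normalized OTF magnitude", {
  g <- midOtf()
  cur <- axialResponse(methodParams("structured", s0 = 1), g)
  ref <- abs(otfAt(g, 1, uGrid(g)))
  expect_equal(cur@intensity, ref / max(ref), tolerance = 1e-9)
  # the half-cutoff frequency is the sectioning optimum
  fw <- vapply(seq(0.25, 1.75, by = 0.25), function(s0)
    fwhm(axialResponse(methodParams("structured", s0 = s0), g)), numeric(1))
  expect_equal(which.min(fw), 4L)  # s0 = 1
})

test_that("hybrid bandwidth tunes sectioning, best near the half-cutoff band", {
  g <- midOtf()
  fw <- vapply(c(0, 0.5, 1, 1.5), function(smin)
    fwhm(axialResponse(methodParams("hybrid", s_min = smin, s_max = 2), g)),
    numeric(1))
  # tunable: wide spread across bandwidths; the [1, 2] band (centred on the
  # half-cutoff optimum) beats both the full band and the narrow cutoff band
  expect_gt(max(fw) / min(fw), 2)
  expect_equal(which.min(fw), 3L)
  expect_error(methodParams("hybrid", s_min = 2, s_max = 2), "structured")
})

test_that("light-sheet response matches its closed form", {
  g <- makeOTFGrid(s_points = 65, u_max = 8, u_points = 401)
  cur <- axialResponse(methodParams("light_sheet", c = 0.8), g)
  expect_equal(fwhm(cur), 2 * 0.8 * sqrt(2 * log(2)), tolerance = 5e-3)
  # half maximum at u = c sqrt(2 ln 2) by construction
  u_half <- 0.8 * sqrt(2 * log(2))
  expect_equal(approx(cur@u, cur@intensity, u_half)$y, 0.5, tolerance = 1e-3)
  expect_lt(fwhm(axialResponse(methodParams("light_sheet", c = 0.5), g)),
            fwhm(axialResponse(methodParams("light_sheet", c = 1.0), g)))
})

test_that("LiMo sections better than line confocal and matches fine quadrature", {
  g <- midOtf()
  limo <- axialResponse(methodParams("limo", beta = 0.5), g)
  lc <- axialResponse(methodParams("line_confocal", beta = 0.5), g)
  expect_lt(fwhm(limo), fwhm(lc))
  # refined-quadrature oracle at u = 5: direct integral of the integrand
  # with otfDefocused() on a fine s grid, independently normalized
  limo_at <- function(u, ns = 801) {
    s <- seq(0, 2, length.out = ns)
    Tv <- otfDefocused(s, rep(u, ns), nquad = 800)
    f <- Tv^2 * sin(0.5 * s + (s == 0)) / (0.5 * s + (s == 0)) *
      (1 - cos(2 * 0.5 * s))
    f[1] <- 0
    sum(f) * (s[2] - s[1])
  }
  ref <- limo_at(5) / limo_at(0)
  got <- approx(limo@u, limo@intensity, 5)$y
  expect_equal(got, ref, tolerance = 0.01)
})

test_that("grid refinement changes FWHM estimates by < 0.5%", {
  g1 <- makeOTFGrid(s_points = 129, u_max = 30, u_points = 151)
  g2 <- makeOTFGrid(s_points = 257, u_max = 30, u_points = 301)
  for (p in list(methodParams("confocal_pinhole", beta = 0.5),
                 methodParams("limo", beta = 0.5),
                 methodParams("structured", s0 = 1))) {
    f1 <- fwhm(axialResponse(p, g1))
    f2 <- fwhm(axialResponse(p, g2))
    expect_lt(abs(f1 - f2) / f2, 0.005, label = p@method)
  }
})

test_that("sectioning ranking reproduces the reference ordering", {
  rk <- sectioningRanking(refOtf(), testCfg())
  expect_identical(rk$method,
                   c("light_sheet", "limo", "confocal", "structured",
                     "hybrid", "two_photon", "line_confocal"))
  # single-method list returns itself
  one <- sectioningRanking(midOtf(),
                           params_set = list(methodParams("limo", beta = 0.5)))
  expect_identical(nrow(one), 1L)
  expect_error(sectioningRanking(midOtf(), params_set = list()), "no methods")
})
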