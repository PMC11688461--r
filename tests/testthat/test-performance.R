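test_that("mosaic time follows the printed formula and its limits", {
  # L = M: a single field takes exactly the exposure time
  expect_equal(mosaicTime(t_m = 0.5, M = 0.67, a = 200, L = 0.67), 0.5)
  # direct arithmetic check
  tr <- sqrt(4 * 0.67 / 200)
  expect_equal(mosaicTime(0.533, 0.67, 200, 5),
               (0.533 + tr) * 25 / 0.67^2 - tr)
  expect_error(mosaicTime(0.5, 0.67, 200, L = 0.3), "smallAreaTime")
})

test_that("mosaic coefficients reproduce the reference-system values", {
  t_spot <- 2048^2 / (512^2 * 30)
  co <- mosaicCoefficients(t_spot, M = 0.67, a = 200)
  expect_equal(round(co$quadratic, 2), 1.45)
  expect_equal(round(co$constant, 2), -0.12)
  expect_equal(round(mosaicCoefficients(0.010, 0.67, 200)$quadratic, 2), 0.28)
})

test_that("strip time: no transition term at L = M, linear in t_s", {
  expect_equal(stripTime(t_s = 4e-7, p = 3.25e-4, M = 0.67, a = 200,
                         L = 0.67),
               0.67^2 * 4e-7 / (3.25e-4 * 0.67))
  t1 <- stripTime(1e-6, 3.25e-4, 0.67, 200, 5)
  t2 <- stripTime(2e-6, 3.25e-4, 0.67, 200, 5)
  fixed <- stripTime(0, 3.25e-4, 0.67, 200, 5)
  expect_equal(t2 - fixed, 2 * (t1 - fixed), tolerance = 1e-12)
})

test_that("line scanning beats point-scanning mosaics across sample sizes", {
  t_spot <- 2048^2 / (512^2 * 30)
  for (L in c(1, 2, 5, 10, 20)) {
    expect_lt(stripTime(t_s = 3.3e-6, p = 3.25e-4, M = 0.67, a = 200, L = L),
              mosaicTime(t_spot, 0.67, 200, L), label = paste("L =", L))
  }
})

test_that("small-area law is quadratic with the camera-limited coefficient", {
  t_spot <- 2048^2 / (512^2 * 30)
  expect_equal(signif(t_spot / 0.67^2, 2), 1.2)
  expect_equal(smallAreaTime(t_spot, M = 0.67, L = 0), 0)
  expect_equal(smallAreaTime(t_spot / 2, 0.67, 0.5),
               smallAreaTime(t_spot, 0.67, 0.5) / 2)
  expect_error(smallAreaTime(0.5, M = 0.67, L = 1), "mosaicTime")
})

test_that("SNR branches evaluate as printed", {
  expect_equal(snrValue("two_photon", f = 4, var_f = 4), 2)
  expect_equal(snrValue("light_sheet", f = 4, var_f = 4), 2)
  # confocal is penalized by the aperture ratio whenever S < S0
  expect_lt(snrValue("confocal", 1, 1, S = 0.25, S0 = 1),
            snrValue("light_sheet", 1, 1))
  expect_equal(snrValue("confocal", 1, 1, S = 0.25, S0 = 1), 0.5)
  m <- c(0.5, 0.7, 1, 1, 0.7, 0.5)
  expect_equal(snrValue("limo", 1, 1, m = m),
               sqrt(2 * (m[3] + m[4]) - (m[1] + m[2] + m[5] + m[6])))
  expect_equal(snrValue("sim", 1, 1, m = m, k = 1),
               (m[3] + m[4] - m[1] - m[6]) * sqrt(3) / 2)
  expect_equal(snrValue("hilo", 1, 1, m = m),
               1 / sqrt((sd(m) / sqrt(2)) / mean(m)))
  expect_error(snrValue("confocal", 1, 0), "var_f")
})

test_that("SNR ranking under the shared modulation profile", {
  rk <- snrRanking()
  expect_identical(rk$method,
                   c("hilo", "limo", "two_photon", "light_sheet", "sim",
                     "line_confocal", "confocal"))
  expect_equal(rk$snr[rk$method == "two_photon"],
               rk$snr[rk$method == "light_sheet"])
})

test_that("penetration depth decays exponentially with the right rates", {
  expect_equal(penetrationPower(0, ls = 100, P0 = 3), 3)
  expect_equal(penetrationPower(0, ls = 100, order = "nonlinear"), 1)
  expect_equal(penetrationPower(100, ls = 100, P0 = 1), exp(-1))
  lin <- penetrationPower(100, ls = 100) / penetrationPower(0, ls = 100)
  nl <- penetrationPower(100, ls = 100, order = "nonlinear")
  expect_equal(nl / lin, exp(-1))
})

test_that("phototoxic dose algebra and scanning invariance", {
  expect_equal(phototoxicity(1, 1, 1), 1)
  expect_equal(phototoxicity(2, 3, 6), 1)
  expect_equal(phototoxicity(2, 1, 1), 2 * phototoxicity(1, 1, 1))
  expect_true(scanningInvariance(1.5, 2, 3, factor = 4))
  expect_error(phototoxicity(1, 1, 0), "S_area")
})
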