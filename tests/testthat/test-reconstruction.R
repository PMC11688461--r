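# helper: a toy stack from explicit line images
toyStack <- function(imgs, pitch = 0.325) {
  A <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (i in seq_along(imgs)) A[, , i] <- imgs[[i]]
  new("RawOffAxisStack", images = A, plane_z = 0,
      scan = scanConfig(n_lines = length(imgs), noise = "none"))
}

test_that("LC returns line 3 unchanged", {
  set.seed(1)
  imgs <- lapply(1:6, function(i) matrix(rexp(64 * 64), 64, 64))
  stk <- toyStack(imgs)
  expect_identical(reconImage(reconLC(stk)), imgs[[3]])
  zero <- toyStack(lapply(1:6, function(i) matrix(0, 8, 8)))
  expect_true(all(reconImage(reconLC(zero)) == 0))
  two <- toyStack(lapply(1:2, function(i) matrix(1, 4, 4)))
  expect_error(reconLC(two), "at least 3")
})

test_that("DSIM cancels modulation-free input and matches its closed form", {
  set.seed(2)
  common <- matrix(rexp(32 * 32), 32, 32)
  flat <- toyStack(lapply(1:6, function(i) common))
  expect_true(all(reconImage(reconDSIM(flat)) == 0))
  imgs <- lapply(1:6, function(i) common * i)
  stk <- toyStack(imgs)
  expect_equal(reconImage(reconDSIM(stk)),
               sqrt(5 * (imgs[[3]] - imgs[[1]])^2), tolerance = 1e-12)
})

test_that("general and simplified DSIM agree on a symmetric point stack", {
  cfg <- testCfg(); scan <- testScan()
  kern <- testKernels()
  p <- pointSource(shape = c(49, 49, 33))
  stk <- simulatePlane(p, cfg, scan, plane_z = 8.25, kernels = kern)
  gen <- reconImage(reconDSIM(stk, reconParams("DSIM",
                                               dsim_form = "general")))
  simp <- reconImage(reconDSIM(stk))
  gen <- gen / max(gen); simp <- simp / max(simp)
  keep <- simp > 0.1 * max(simp)
  expect_lt(max(abs(gen[keep] - simp[keep])), 0.05)
})

test_that("DHiLo limits: gamma = 0 identity, flat-field algebra", {
  set.seed(3)
  imgs <- lapply(1:6, function(i) matrix(rexp(32 * 32), 32, 32))
  stk <- toyStack(imgs)
  g0 <- reconDHiLo(stk, reconParams("DHiLo", gamma = 0))
  expect_equal(reconImage(g0), pmax(imgs[[3]], 0), tolerance = 1e-9)
  flat <- toyStack(lapply(1:6, function(i) matrix(2, 32, 32)))
  half <- reconDHiLo(flat, reconParams("DHiLo", gamma = 0.5))
  expect_equal(reconImage(half), matrix(1, 32, 32), tolerance = 1e-9)
  one <- reconDHiLo(flat, reconParams("DHiLo", gamma = 1))
  expect_equal(max(abs(reconImage(one))), 0, tolerance = 1e-9)
  expect_error(reconDHiLo(stk, reconParams("DHiLo", filter_cutoff = 10)),
               "Nyquist")
})

test_that("LiMo cancels equal lines and is linear before clipping", {
  set.seed(4)
  common <- matrix(rexp(32 * 32), 32, 32)
  flat <- toyStack(lapply(1:6, function(i) common))
  expect_true(all(reconImage(reconLiMo(flat)) == 0))
  A <- lapply(1:6, function(i) matrix(rexp(32 * 32), 32, 32))
  B <- lapply(1:6, function(i) matrix(rexp(32 * 32), 32, 32))
  mixed <- toyStack(Map(function(a, b) 3 * a + b, A, B))
  lin <- reconUnclipped(reconLiMo(mixed))
  expect_equal(lin, 3 * reconUnclipped(reconLiMo(toyStack(A))) +
                 reconUnclipped(reconLiMo(toyStack(B))), tolerance = 1e-9)
  five <- toyStack(lapply(1:5, function(i) common))
  expect_error(reconLiMo(five), "6 detector lines")
})

test_that("LiMo keeps a small positive in-focus residual from a defocused sheet", {
  cfg <- testCfg(); scan <- testScan()
  kern <- testKernels()
  infoc <- fluorescentSheet(z0 = 8.25, shape = c(48, 48, 33))
  s_in <- simulatePlane(infoc, cfg, scan, plane_z = 8.25, kernels = kern)
  r_in <- mean(reconImage(reconLiMo(s_in)))
  deep <- fluorescentSheet(z0 = 14.25, shape = c(48, 48, 33))
  s_dp <- simulatePlane(deep, cfg, scan, plane_z = 8.25, kernels = kern)
  r_dp <- mean(reconImage(reconLiMo(s_dp)))
  near <- fluorescentSheet(z0 = 8.75, shape = c(48, 48, 33))
  s_nr <- simulatePlane(near, cfg, scan, plane_z = 8.25, kernels = kern)
  r_nr <- mean(reconImage(reconLiMo(s_nr)))
  expect_gt(r_in, 0)
  expect_gt(r_nr, 0)          # depth-of-focus residual, not exactly zero
  expect_lt(r_dp / r_in, 0.01)  # far-defocused sheet is near-cancelled
  expect_lt(r_nr, r_in)
})

test_that("sbr implements the masked mean ratio with its edge cases", {
  img <- matrix(2, 16, 16); img[5:8, 5:8] <- 10
  sig <- matrix(FALSE, 16, 16); sig[5:8, 5:8] <- TRUE
  bg <- !sig
  expect_equal(sbr(img, sig, bg), 5)
  expect_equal(sbr(2 * img, sig, bg), 5)      # scale invariant
  flat <- matrix(3, 16, 16)
  expect_equal(sbr(flat, sig, bg), 1)
  expect_error(sbr(img, sig, sig), "disjoint")
  expect_error(sbr(img, matrix(FALSE, 16, 16), bg), "non-empty")
})

test_that("reconstruct() dispatches and scores reproducibly at small scale", {
  res <- runPipeline(runConfig(seed = 2, shape = c(64, 64, 32), n_paths = 6))
  expect_identical(res$summary$method, c("LC", "DSIM", "DHiLo", "LiMo"))
  expect_true(all(is.finite(res$summary$sbr)))
  res2 <- runPipeline(runConfig(seed = 2, shape = c(64, 64, 32), n_paths = 6))
  expect_identical(res$summary, res2$summary)
})
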