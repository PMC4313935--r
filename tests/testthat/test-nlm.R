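test_that("mode defaults set the smoothing bandwidth multiples", {
  expect_equal(nlm_params("nlm")$h_factor, 1.0)
  expect_equal(nlm_params("vnlm_b")$h_factor, 0.8)
  expect_equal(nlm_params("vnlm_d")$h_factor, 1.2)
  expect_equal(nlm_params("nlm")$search_radius, 2L)  # 5x5x5 region
  expect_equal(nlm_params("nlm")$patch_radius, 1L)   # 3x3x3 window
  expect_equal(nlm_params("nlm")$rho, 1.0)
  expect_error(nlm_params("nlm", search_radius = 0, patch_radius = 1))
  expect_error(nlm_params("nlm", rho = 0))
})

test_that("patch distance matches the naive double-loop computation", {
  set.seed(101)
  vol <- array(runif(7 * 7 * 7), c(7, 7, 7))
  p <- nlm_params("nlm", sigma = 1)
  for (k in 1:10) {
    i <- sample(7, 3, replace = TRUE)
    j <- sample(7, 3, replace = TRUE)
    if (all(i == j)) next
    expect_equal(patch_distance(vol, i, j, p),
                 oracle_patch_distance(list(vol), i, j, 1L, 1.0),
                 tolerance = 1e-12)
  }
  # identical patches -> 0; constant offset c -> c^2 under unit-mass weights
  flat <- array(3, c(7, 7, 7))
  expect_equal(patch_distance(flat, c(2, 2, 2), c(5, 5, 3), p), 0)
  step <- flat; step[5:7, , ] <- 3 + 1.5
  expect_equal(patch_distance(step, c(2, 4, 4), c(6, 4, 4), p), 1.5^2,
               tolerance = 1e-12)
})

test_that("NLM preserves constants and homogeneous regions", {
  p <- nlm_params("nlm", sigma = 1)
  flat <- array(5, c(8, 8, 8))
  expect_equal(nlm3d(flat, p), flat, tolerance = 1e-12)
  # interior voxel of a noiseless homogeneous region stays put
  vol <- array(5, c(9, 9, 9)); vol[1, 1, 1] <- 50
  expect_equal(nlm3d(vol, p)[5, 5, 5], 5, tolerance = 1e-12)
})

test_that("filters match the naive references on random volumes", {
  set.seed(2024)
  for (k in 1:20) {
    V <- sample(1:5, 1)
    arr <- array(runif(7 * 7 * 7 * V), c(7, 7, 7, V))
    h <- runif(1, 0.2, 0.8)
    ref <- oracle_vnlm(arr, 2L, 1L, 1.0, h)
    got <- if (V == 1L) {
      array(nlm3d(array(arr, c(7, 7, 7)),
                  nlm_params("nlm", h_factor = 1, sigma = h)), dim(arr))
    } else {
      vnlm(arr, nlm_params("vnlm_d", h_factor = 1, sigma = h,
                           rician_correction = FALSE))
    }
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("denoised values are convex combinations of their search region", {
  set.seed(5)
  vol <- array(runif(10 * 10 * 6, 10, 20), c(10, 10, 6))
  out <- nlm3d(vol, nlm_params("nlm", sigma = 2))
  t <- 2L
  for (k in 1:50) {
    c0 <- c(sample(10, 1), sample(10, 1), sample(6, 1))
    ix <- dkiphantom:::reflect_index(seq(c0[1] - t, c0[1] + t), 10)
    iy <- dkiphantom:::reflect_index(seq(c0[2] - t, c0[2] + t), 10)
    iz <- dkiphantom:::reflect_index(seq(c0[3] - t, c0[3] + t), 6)
    reg <- vol[ix, iy, iz]
    v <- out[c0[1], c0[2], c0[3]]
    expect_gte(v, min(reg) - 1e-12)
    expect_lte(v, max(reg) + 1e-12)
  }
})

test_that("Rician unbiasing applies the second-moment correction", {
  expect_equal(rician_unbias(array(10, c(2, 2, 2)), 5)[1], sqrt(50),
               tolerance = 1e-12)
  expect_equal(rician_unbias(array(3, c(2, 2, 2)), 5)[1], 0)   # clamped
  x <- array(runif(8), c(2, 2, 2))
  expect_equal(rician_unbias(x, 0), x)                         # identity
  expect_error(rician_unbias(x, -1), "nonnegative")
})

test_that("vector NLM with one channel reduces to scalar NLM", {
  set.seed(31)
  vol <- array(runif(6 * 6 * 6), c(6, 6, 6))
  a <- nlm3d(vol, nlm_params("nlm", h_factor = 1.0, sigma = 0.3))
  b <- vnlm(list(vol), nlm_params("vnlm_b", h_factor = 1.0, sigma = 0.3,
                                  rician_correction = FALSE))[[1L]]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("identical channels are denoised like the single volume", {
  set.seed(32)
  vol <- array(runif(6 * 6 * 6), c(6, 6, 6))
  ref <- nlm3d(vol, nlm_params("nlm", h_factor = 1.0, sigma = 0.3))
  out <- vnlm(list(vol, vol, vol),
              nlm_params("vnlm_d", h_factor = 1.0, sigma = 0.3,
                         rician_correction = FALSE))
  for (ch in out) expect_equal(ch, ref, tolerance = 1e-11)
})

test_that("dataset-level denoising dispatches groups per mode", {
  ds <- tiny_dataset(n_directions = 6, bvals = c(0, 1000, 2000),
                     grid = c(6L, 6L, 6L))
  # noise-free constant-per-volume dataset: every mode is (numerically) a no-op
  for (mode in c("nlm", "vnlm_b", "vnlm_d")) {
    den <- denoise_dwi(ds, mode, sigma = 1e-9)
    expect_equal(den$signal, ds$signal, tolerance = 1e-6)
  }
  expect_error(denoise_dwi(ds, "bogus"))
})

test_that("second-moment averaging matches the oracle on squared intensities", {
  set.seed(71)
  vol <- array(runif(7 * 7 * 7, 5, 15), c(7, 7, 7))
  h <- 2
  got <- nlm3d(vol, nlm_params("nlm", h_factor = 1, sigma = h),
               second_moment = TRUE)
  # weights from magnitude patches, averages of squares, square root
  ref <- oracle_vnlm_sq(array(vol, c(7, 7, 7, 1)), 2L, 1L, 1.0, h)
  expect_lt(max(abs(got - array(ref, dim(vol)))), 1e-10)
})

test_that("UNLM is closer to the truth than raw NLM on Rician-noisy data", {
  # constant-100 cube, sigma = 10: bias subtraction must help
  wins <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    noisy <- add_rician(array(100, c(22, 22, 22)), 10, seed = 300 + r)
    nl <- nlm3d(noisy, nlm_params("nlm", sigma = 10))
    un <- rician_unbias(nlm3d(noisy, nlm_params("nlm", sigma = 10),
                              second_moment = TRUE), 10)
    wins <- wins + (abs(mean(un) - 100) < abs(mean(nl) - 100))
  }
  expect_gte(wins, 19L)
})
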