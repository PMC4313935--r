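test_that("forward signal model reproduces hand-computed values", {
  # b = 0: exponent vanishes
  expect_equal(predict_dki_signal(100, 0, 2e-3, 3), 100)
  # K = 0 reduces to the mono-exponential decay
  expect_equal(predict_dki_signal(100, 1000, 1e-3, 0), 100 * exp(-1),
               tolerance = 1e-12)
  # kurtosis term, hand-evaluated exponent -2.5 + 6.25/6 = -1.458333...
  expect_equal(predict_dki_signal(100, 2500, 1e-3, 1), 23.2623657917,
               tolerance = 1e-9)
})

test_that("signal is strictly decreasing in b within the kurtosis regime", {
  # the quadratic exponent bottoms out at b = 3/(D K); the model is a valid
  # decay only below that bound
  for (D in c(1e-4, 1e-3, 3e-3)) for (K in c(0, 1.5, 3)) {
    bmax <- if (K > 0) min(2500, 3 / (D * K)) else 2500
    b <- seq(0, bmax, length.out = 40)
    s <- predict_dki_signal(100, b, D, K)
    expect_true(all(diff(s) < 0), info = sprintf("D=%g K=%g", D, K))
  }
})

test_that("noiseless decay curves are inverted to high precision", {
  b <- c(0, 500, 1000, 1500, 2000, 2500)
  for (D in c(1e-4, 1.2e-3, 3e-3)) for (K in c(0, 0.8, 3)) {
    s <- predict_dki_signal(100, b, D, K)
    fit <- fit_dki_direction(s, b)
    expect_lt(abs(fit$D - D) / D, 1e-8)
    expect_lt(abs(fit$K - K) / max(K, 1), 1e-8)
    expect_true(fit$valid)
  }
})

test_that("baseline plus two nonzero b-values solves the 2x2 system exactly", {
  # frozen from the symbolic solution of
  # -1000 D + (1000^2/6) b = ln 0.6 ; -2000 D + (2000^2/6) b = ln 0.4
  fit <- fit_dki_direction(c(100, 60, 40), c(0, 1000, 2000))
  expect_equal(fit$D, 0.000563505881595, tolerance = 1e-10)
  expect_equal(fit$K, 0.995410541144, tolerance = 1e-9)
})

test_that("degenerate decay curves are flagged", {
  # constant signal: D = 0, K = 0, invalid
  fit <- fit_dki_direction(c(100, 100, 100, 100), c(0, 500, 1000, 1500))
  expect_equal(fit$D, 0)
  expect_equal(fit$K, 0)
  expect_false(fit$valid)
  expect_error(fit_dki_direction(c(100, 50), c(0, 1000)), "3 distinct")
  expect_error(fit_dki_direction(c(0, 0, 0), c(0, 1000, 2000)), "all-zero")
})

test_that("whole-dataset directional fitting recovers the ground truth", {
  bundle <- full_bundle()
  ds <- bundle$noise_free
  dm <- fit_dki_directions(ds)
  mask <- ds$brain_mask & array(bundle$directional$valid[, , , 1],
                                dim(ds$brain_mask))
  idx <- rep(mask, dim(dm$D)[4])
  expect_lt(max(abs(dm$D[idx] - bundle$directional$D[idx])), 1e-10)
  expect_lt(max(abs(dm$K[idx] - bundle$directional$K[idx])), 1e-7)
  # masked-out voxels are zero and invalid
  outside <- !rep(as.vector(ds$brain_mask), dim(dm$D)[4])
  expect_true(all(dm$D[outside] == 0))
  expect_false(any(dm$valid[, , , 1][!ds$brain_mask]))
})

test_that("direction averaging gives MD and MK", {
  ds <- tiny_dataset(D = 1e-3, K = 0.8)
  mm <- mean_dki_maps(fit_dki_directions(ds))
  expect_equal(max(abs(mm$MD - 1e-3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(mm$MK - 0.8)), 0, tolerance = 1e-8)
  # mean of K = {0.5, 1.5} over two directions is 1.0
  dm <- structure(list(D = array(1e-3, c(1, 1, 1, 2)),
                       K = array(c(0.5, 1.5), c(1, 1, 1, 2)),
                       valid = array(TRUE, c(1, 1, 1, 2)),
                       directions = rbind(c(1, 0, 0), c(0, 1, 0)),
                       stage = "raw"), class = "directional_maps")
  expect_equal(mean_dki_maps(dm)$MK[1], 1.0)
  # all-invalid voxel is invalid in the output
  dm$valid[] <- FALSE
  expect_false(mean_dki_maps(dm)$valid[1])
})

test_that("tensor fit and directional resynthesis are mutually inverse", {
  bundle <- full_bundle()
  dm <- bundle$directional
  tf <- fit_dki_tensors(dm)
  back <- tensors_to_directional(tf, dm$directions)
  mask <- rep(bundle$noise_free$brain_mask, dim(dm$D)[4]) & dm$valid
  expect_lt(max(abs(back$D[mask] - dm$D[mask])), 1e-10)
  expect_lt(max(abs(back$K[mask] - dm$K[mask])), 1e-6)
  # ground-truth tensors themselves are recovered inside the brain
  truth <- attr(bundle, "phantom")$tensors
  bm <- rep(bundle$noise_free$brain_mask, 6)
  expect_lt(max(abs(tf$Dt[bm] - truth$Dt[bm])), 1e-12)
})

test_that("isotropic tensors give direction-independent maps", {
  d <- 1.5e-3; w <- 0.7
  tf <- structure(list(
    Dt = array(rep(c(d, d, d, 0, 0, 0), each = 8), c(2, 2, 2, 6)),
    Wt = array(rep(dkiphantom:::isotropic_kurtosis_tensor(w), each = 8),
               c(2, 2, 2, 15)),
    MD = array(d, c(2, 2, 2)), MK = array(w, c(2, 2, 2)),
    valid = array(TRUE, c(2, 2, 2))), class = "tensor_field")
  dm <- tensors_to_directional(tf, dkiphantom:::fibonacci_sphere(20))
  expect_equal(max(abs(dm$D - d)), 0, tolerance = 1e-15)
  expect_equal(max(abs(dm$K - w)), 0, tolerance = 1e-12)
})

test_that("prolate tensor evaluates to its axial eigenvalue along the fiber", {
  dt6 <- dkiphantom:::prolate_tensor(c(0, 0, 1), 1.7e-3, 0.3e-3)
  tf <- structure(list(Dt = array(rep(dt6, each = 1), c(1, 1, 1, 6)),
                       Wt = array(0, c(1, 1, 1, 15)),
                       MD = array(mean(dt6[1:3]), c(1, 1, 1)),
                       MK = array(0, c(1, 1, 1)),
                       valid = array(TRUE, c(1, 1, 1))), class = "tensor_field")
  dm <- tensors_to_directional(tf, rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(dm$D[1, 1, 1, 1], 1.7e-3, tolerance = 1e-12)
  expect_equal(dm$D[1, 1, 1, 2], 0.3e-3, tolerance = 1e-12)
})

test_that("too few directions raise a rank error", {
  dirs5 <- dkiphantom:::fibonacci_sphere(5)
  dm <- structure(list(D = array(1e-3, c(1, 1, 1, 5)),
                       K = array(0.5, c(1, 1, 1, 5)),
                       valid = array(TRUE, c(1, 1, 1, 5)),
                       directions = dirs5, stage = "raw"),
                  class = "directional_maps")
  # 5 directions: design matrix rank is at most 5 < 6
  expect_equal(qr(dkiphantom:::dt_design(dirs5))$rank, 5L)
  expect_error(fit_dki_tensors(dm), "rank-deficient")
})

test_that("a diffusion tensor needs seven measurements", {
  expect_identical(min_tensor_measurements(), 7L)
})

test_that("direct averaging and the tensor route agree on isotropic data", {
  ds <- tiny_dataset(n_directions = 20, bvals = c(0, 1000, 2000, 2500),
                     D = 0.9e-3, K = 0.9)
  dm <- fit_dki_directions(ds)
  direct <- mean_dki_maps(dm)
  tensor <- mean_dki_maps(tensors_to_directional(fit_dki_tensors(dm),
                                                 dm$directions))
  expect_equal(direct$MD, tensor$MD, tolerance = 1e-10)
  expect_equal(direct$MK, tensor$MK, tolerance = 1e-8)
})
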