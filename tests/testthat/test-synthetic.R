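test_that("gradient scheme generation counts volumes correctly", {
  # one baseline + 30 directions x 5 nonzero b-values
  expect_equal(make_gradient_scheme(30, c(0, 500, 1000, 1500, 2000, 2500))$n_volumes,
               151L)
  expect_equal(make_gradient_scheme(12, c(0, 1000, 2000))$n_volumes, 25L)
  sch <- make_gradient_scheme(30, c(0, 1000))
  nrm <- sqrt(rowSums(sch$bvecs[sch$bvals > 0, ]^2))
  expect_lt(max(abs(nrm - 1)), 1e-12)
  expect_error(make_gradient_scheme(5, c(0, 1000)), "at least 6")
  # pure function: identical inputs give identical vectors
  expect_identical(make_gradient_scheme(20, c(0, 1000, 2000)),
                   make_gradient_scheme(20, c(0, 1000, 2000)))
})

test_that("the default tensor phantom is physiologically plausible", {
  ph <- make_tensor_phantom()
  nvox <- prod(dim(ph$S0))
  Dt <- matrix(ph$tensors$Dt, nrow = nvox)
  brain <- as.vector(ph$brain_mask)
  ev <- t(apply(Dt[brain, ], 1, function(d6) {
    M <- matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6],
                  d6[5], d6[6], d6[3]), 3, 3)
    eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }))
  expect_gte(min(ev), 0.3e-3 - 1e-12)
  expect_lte(max(ev), 3.0e-3 + 1e-12)
  # background voxels carry no signal and are disjoint from the brain
  expect_true(all(ph$S0[ph$background_mask] == 0))
  expect_false(any(ph$brain_mask & ph$background_mask))
})

test_that("forward synthesis plus fitting is the identity on noiseless data", {
  bundle <- full_bundle()
  ds <- bundle$noise_free
  mm <- mean_dki_maps(fit_dki_directions(ds))
  truth <- mean_dki_maps(bundle$directional, only_valid = FALSE)
  m <- ds$brain_mask
  expect_lt(max(abs(mm$MD - truth$MD)[m]), 1e-11)
  expect_lt(max(abs(mm$MK - truth$MK)[m]), 1e-7)
  # isotropic region: all same-b volumes identical there
  ph <- attr(bundle, "phantom")
  gm <- ds$brain_mask & abs(ph$tensors$MD - 0.9e-3) < 1e-9
  sp <- split_volumes(ds, by = "b_value")
  grp <- sp$groups[[1L]]
  ref <- ds$signal[, , , grp[1L]][gm]
  for (v in grp[-1L]) expect_equal(ds$signal[, , , v][gm], ref,
                                   tolerance = 1e-12)
  # zero-background voxels are zero at every b
  expect_true(all(ds$signal[rep(ph$background_mask, ds$scheme$n_volumes)] == 0))
})

test_that("hand-computed CSF decay matches the synthesized signal", {
  # D = 3.0e-3, K = 0.1, b = 1000: exponent -3 + 1e6 * 9e-6 * 0.1 / 6 = -2.85
  ph <- make_tensor_phantom()
  csf <- which(ph$brain_mask & abs(ph$tensors$MD - 3.0e-3) < 1e-9,
               arr.ind = TRUE)[1, ]
  sch <- make_gradient_scheme(12, c(0, 1000))
  ds <- synthesize_dwi(ph$tensors, ph$S0, sch, ph$voxel_size, ph$brain_mask)
  s0 <- ds$signal[csf[1], csf[2], csf[3], 1]
  sb <- ds$signal[csf[1], csf[2], csf[3], 2]
  expect_equal(sb, s0 * exp(-2.85), tolerance = 1e-10)
})

test_that("parameters are identifiable from noisy data at high SNR", {
  bundle <- full_bundle()
  ph <- attr(bundle, "phantom")
  ds <- bundle$noise_free
  truth <- mean_dki_maps(bundle$directional, only_valid = FALSE)
  region_err <- function(sigma, seed, region) {
    noisy <- add_rician(ds$signal, sigma, seed = seed)
    nds <- dwi_dataset(noisy, ds$scheme, ds$voxel_size, ds$brain_mask,
                       ds$background_mask)
    mm <- mean_dki_maps(fit_dki_directions(nds))
    c(MD = abs(median(mm$MD[region]) - median(truth$MD[region])) /
        median(truth$MD[region]),
      MK = abs(median(mm$MK[region]) - median(truth$MK[region])) /
        median(truth$MK[region]))
  }
  gm <- ds$brain_mask & abs(ph$tensors$MD - 0.9e-3) < 1e-9
  err_gm <- region_err(320 / 30, 42, gm)   # SNR 30 in the isotropic compartment
  expect_lt(err_gm[["MD"]], 0.02)
  expect_lt(err_gm[["MK"]], 0.05)
  # anisotropic fibers need more SNR: Rician noise inflates kurtosis along
  # low-D radial directions at high b
  wm <- ds$brain_mask & abs(ph$tensors$MD - (1.7e-3 + 2 * 0.3e-3) / 3) < 1e-9
  err_wm <- region_err(5, 42, wm)          # SNR ~ 54
  expect_lt(err_wm[["MD"]], 0.02)
  expect_lt(err_wm[["MK"]], 0.05)
})
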