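test_that("gradient_scheme validates and normalizes its inputs", {
  sch <- gradient_scheme(c(0, 1000, 1000), rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)))
  expect_equal(sch$n_volumes, 3L)
  expect_equal(sqrt(rowSums(sch$bvecs[2:3, ]^2)), c(1, 1), tolerance = 1e-12)
  # zero vector only allowed at b = 0
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero gradient")
  expect_error(gradient_scheme(c(0, -5), rbind(c(0, 0, 0), c(1, 0, 0))),
               "negative")
  expect_error(gradient_scheme(c(0, 1000, 2000), rbind(c(0, 0, 0), c(1, 0, 0))),
               "mismatch")
})

test_that("volume grouping partitions DW volumes by b-value and by direction", {
  sch <- make_gradient_scheme(30, c(0, 500, 1000, 1500, 2000, 2500))
  by_d <- split_volumes(sch, by = "direction")
  by_b <- split_volumes(sch, by = "b_value")
  expect_length(by_d$groups, 30L)
  expect_true(all(lengths(by_d$groups) == 5L))
  expect_length(by_b$groups, 5L)
  expect_true(all(lengths(by_b$groups) == 30L))
  dw <- which(sch$bvals > 0)
  # partition property: every nonzero-b index appears exactly once
  expect_setequal(unlist(by_d$groups), dw)
  expect_setequal(unlist(by_b$groups), dw)
  expect_equal(by_d$baseline, which(sch$bvals == 0))
})

test_that("antipodal directions are identified when grouping", {
  sch <- gradient_scheme(c(0, 1000, 2000),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  sp <- split_volumes(sch, by = "direction")
  expect_length(sp$groups, 1L)
  expect_equal(sort(sp$groups[[1L]]), c(2L, 3L))
})

test_that("baseline-only schemes yield an empty grouping", {
  sch <- gradient_scheme(c(0, 0), matrix(0, 2, 3))
  sp <- split_volumes(sch, by = "direction")
  expect_length(sp$groups, 0L)
  expect_equal(sp$baseline, 1:2)
})

test_that("NIfTI + bval/bvec round trip preserves the dataset", {
  ds <- tiny_dataset()
  pre <- file.path(tempdir(), "rt")
  write_dwi_dataset(ds, pre)
  rt <- read_dwi_dataset(paste0(pre, ".nii.gz"), paste0(pre, ".bval"),
                         paste0(pre, ".bvec"),
                         brain_mask_path = paste0(pre, "_brain_mask.nii.gz"))
  expect_identical(dim(rt$signal), dim(ds$signal))
  expect_equal(rt$signal, ds$signal, tolerance = 0)       # bit-identical
  expect_equal(rt$voxel_size, ds$voxel_size, tolerance = 1e-6)
  expect_equal(rt$scheme$bvals, ds$scheme$bvals)
  expect_lt(max(abs(rt$scheme$bvecs - ds$scheme$bvecs)), 1e-6)
  expect_equal(rt$brain_mask, ds$brain_mask)
})

test_that("a 1x1x1 single-direction dataset survives the round trip", {
  sch <- gradient_scheme(c(0, rep(1000, 6)),
                         rbind(c(0, 0, 0), dkiphantom:::fibonacci_sphere(6)))
  ds <- dwi_dataset(array(runif(7, 10, 20), c(1, 1, 1, 7)), sch)
  pre <- file.path(tempdir(), "rt1")
  write_dwi_dataset(ds, pre)
  rt <- read_dwi_dataset(paste0(pre, ".nii.gz"), paste0(pre, ".bval"),
                         paste0(pre, ".bvec"))
  expect_equal(rt$signal, ds$signal, tolerance = 0)
  expect_equal(rt$scheme$bvals, ds$scheme$bvals)
})

test_that("baseline averaging collapses repeated b0 volumes", {
  sch <- gradient_scheme(c(0, 0, 1000, 2000),
                         rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 0)))
  sig <- array(1, c(2, 2, 2, 4))
  sig[, , , 1] <- 90; sig[, , , 2] <- 110
  ds <- average_baselines(dwi_dataset(sig, sch))
  expect_equal(ds$scheme$n_volumes, 3L)
  expect_true(all(ds$signal[, , , 1] == 100))
})

test_that("dataset invariants are enforced", {
  sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(dwi_dataset(array(-1, c(2, 2, 2, 2)), sch), "negative")
  expect_error(dwi_dataset(array(NA_real_, c(2, 2, 2, 2)), sch), "finite")
  expect_error(dwi_dataset(array(1, c(2, 2, 2, 3)), sch), "mismatch")
  m <- array(TRUE, c(2, 2, 2))
  expect_error(dwi_dataset(array(1, c(2, 2, 2, 2)), sch,
                           brain_mask = m, background_mask = m), "overlap")
})
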