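# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# default synthetic phantom under the benchmark acquisition (12 directions)
bench_bundle <- function() {
  if (is.null(.fixture_env$bench)) .fixture_env$bench <- default_phantom_bundle()
  .fixture_env$bench
}

# default phantom under the 30-direction, 6-b-value acquisition
full_bundle <- function() {
  if (is.null(.fixture_env$full)) {
    ph <- make_tensor_phantom()
    sch <- make_gradient_scheme(30, c(0, 500, 1000, 1500, 2000, 2500))
    b <- phantom_from_tensors(ph$tensors, ph$S0, sch, ph$voxel_size,
                              ph$brain_mask, ph$background_mask)
    attr(b, "phantom") <- ph
    .fixture_env$full <- b
  }
  .fixture_env$full
}

# tiny 7-direction isotropic dataset for I/O and fitting unit tests
tiny_dataset <- function(n_directions = 8, bvals = c(0, 1000, 2000),
                         grid = c(5L, 5L, 4L), D = 1e-3, K = 0.8, S0 = 100) {
  sch <- make_gradient_scheme(n_directions, bvals)
  sig <- array(0, c(grid, sch$n_volumes))
  for (v in seq_len(sch$n_volumes))
    sig[, , , v] <- predict_dki_signal(S0, sch$bvals[v], D, K)
  dwi_dataset(sig, sch, voxel_size = c(2, 2, 3),
              brain_mask = array(TRUE, grid))
}
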