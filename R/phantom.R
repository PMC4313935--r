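#' Gaussian smoothing configuration
#'
#' @param fwhm_mm full width at half maximum of the Gaussian kernel, in mm
#'   (`> 0`; `FWHM = 2 sqrt(2 ln 2) * sd`).
#' @param boundary boundary handling; only `"mirror"` is supported (keeps
#'   patch statistics stationary near edges).
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(fwhm_mm = 2, boundary = "mirror") {
  stopifnot(fwhm_mm > 0, identical(boundary, "mirror"))
  structure(list(fwhm_mm = fwhm_mm, boundary = boundary),
            class = "smoothing_config")
}

FWHM_TO_SD <- 2 * sqrt(2 * log(2))  # about 2.35482

#' Separable 3D Gaussian smoothing with mm-specified FWHM
#'
#' Smooths a 3D map with a separable Gaussian whose per-axis standard
#' deviation in voxels is `(fwhm_mm / (2 sqrt(2 ln 2))) / voxel_size[axis]`,
#' so anisotropic voxels get anisotropic voxel-space kernels representing an
#' isotropic mm-space kernel. Boundaries are mirror-padded; the kernel is
#' normalized to unit mass.
#'
#' @param map 3D numeric array.
#' @param cfg a [smoothing_config()] (or a single FWHM in mm).
#' @param voxel_size numeric 3-vector, mm.
#' @return Smoothed 3D array.
#' @export
gaussian_smooth_fwhm <- function(map, cfg = smoothing_config(2), voxel_size = c(1, 1, 1)) {
  if (is.numeric(cfg)) cfg <- smoothing_config(cfg)
  stopifnot(length(dim(map)) == 3L, all(is.finite(map)))
  sd_vox <- (cfg$fwhm_mm / FWHM_TO_SD) / voxel_size
  out <- map
  for (axis in 1:3) {
    s <- sd_vox[axis]
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dim(out)[axis]
    idx <- vapply(seq(-r, r), function(off) reflect_index(seq_len(n) + off, n),
                  integer(n))                       # n x (2r+1)
    sl <- function(m, ix) switch(axis,
                                 m[ix, , , drop = FALSE],
                                 m[, ix, , drop = FALSE],
                                 m[, , ix, drop = FALSE])
    acc <- array(0, dim(out))
    for (j in seq_along(k)) acc <- acc + k[j] * sl(out, idx[, j])
    out <- acc
  }
  out
}

#' Build a tensor-consistent noise-free phantom from a DKI dataset
#'
#' The construction pipeline that turns a (noisy, real or synthetic) DKI
#' acquisition into a noise-free, tensor-consistent digital phantom:
#' \enumerate{
#'   \item denoise every volume with the unbiased NLM filter
#'     (`h = 1.0 sigma`); skipped when `sigma = 0` (already noise-free);
#'   \item (repeat averaging is assumed done upstream, e.g. via
#'     [average_baselines()]);
#'   \item estimate per-direction D and K maps;
#'   \item smooth the D maps with a 3D Gaussian (default 2 mm FWHM), giving D';
#'   \item re-estimate K' per direction with D' held fixed (one-parameter
#'     least squares on `ln(S/S0) + b D'` against `b^2/6`) — K is never
#'     smoothed directly, because noise in small-D voxels would contaminate
#'     it;
#'   \item fit diffusion + kurtosis tensors from (D', K') and re-evaluate
#'     them at the acquisition directions, giving D'' and K'';
#'   \item synthesize the noise-free DW volumes from D'', K'' and the
#'     denoised baseline (negative K'' clamped to 0 so the ground truth is
#'     physically plausible; the clamp count is reported in provenance).
#' }
#' Rician noise is then added separately with
#' [make_noisy_realizations()] / [add_rician()].
#'
#' @param ds a [dwi_dataset()] with a `brain_mask`.
#' @param nlm an [nlm_params()] for step 1 (defaults: plain NLM, h = 1.0 sigma).
#' @param smooth a [smoothing_config()], or `0` to bypass smoothing.
#' @param fit a [fit_options()].
#' @param sigma noise level of the input; `NULL` estimates it from the
#'   background mask; `0` declares the input noise-free and skips step 1.
#' @param max_invalid_frac abort threshold: any stage leaving more than this
#'   fraction of brain voxels invalid stops with a named-stage diagnostic.
#' @return A `phantom_bundle`: `noise_free` ([dwi_dataset()]), `tensors`
#'   (`tensor_field`), `directional` (the D''/K'' maps actually used, with
#'   the K clamp applied), `S0` (3D baseline map), `sigma`, and `provenance`.
#' @export
construct_phantom <- function(ds, nlm = nlm_params("nlm"),
                              smooth = smoothing_config(2),
                              fit = fit_options(), sigma = NULL,
                              max_invalid_frac = 0.2) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (is.null(ds$brain_mask)) stop("construct_phantom requires a brain_mask")
  if (is.null(sigma)) {
    if (is.null(ds$background_mask))
      stop("sigma not given and no background_mask to estimate it from")
    b0 <- which(ds$scheme$bvals == 0)[1L]
    sigma <- estimate_sigma(ds$signal[, , , b0], ds$background_mask)
  }
  nbrain <- sum(ds$brain_mask)
  check_stage <- function(invalid, stage) {
    frac <- sum(invalid & ds$brain_mask) / nbrain
    if (frac > max_invalid_frac)
      stop(sprintf("stage '%s' invalidated %.1f%% of brain voxels (limit %.0f%%)",
                   stage, 100 * frac, 100 * max_invalid_frac))
  }
  # (1) UNLM denoising of every volume
  den <- if (sigma > 0) denoise_dwi(ds, "nlm", nlm, sigma = sigma) else ds
  # (3) directional D, K
  dm <- fit_dki_directions(den, fit)
  check_stage(!apply(dm$valid, 1:3, any), "directional fit")
  # (4) smooth D -> D'
  bypass <- is.numeric(smooth) && length(smooth) == 1L && smooth == 0
  Dp <- dm$D
  if (!bypass) {
    if (is.numeric(smooth)) smooth <- smoothing_config(smooth)
    for (g in seq_len(dim(Dp)[4]))
      Dp[, , , g] <- gaussian_smooth_fwhm(Dp[, , , g], smooth, den$voxel_size)
  }
  # (5) recompute K' with D' fixed
  Kp <- refit_k_fixed_d(den, dm, Dp, fit)
  dmp <- structure(list(D = Dp, K = Kp, valid = dm$valid,
                        directions = dm$directions, stage = "smoothed"),
                   class = "directional_maps")
  # (6) tensors, then D'', K'' at the acquisition directions
  tf <- fit_dki_tensors(dmp)
  dpp <- tensors_to_directional(tf, dm$directions)
  n_clamped <- sum(dpp$K < 0 & as.vector(ds$brain_mask))
  dpp$K <- pmax(dpp$K, 0)
  dpp$stage <- "tensor"
  # (7) synthesize the noise-free volumes
  b0_idx <- which(den$scheme$bvals == 0)
  S0 <- apply(den$signal[, , , b0_idx, drop = FALSE], 1:3, mean)
  S0[!ds$brain_mask] <- 0
  noise_free <- synth_from_directional(dpp, S0, den$scheme, ds$brain_mask)
  bundle <- structure(list(
    noise_free = dwi_dataset(noise_free, den$scheme, den$voxel_size,
                             ds$brain_mask, ds$background_mask),
    tensors = tf, directional = dpp, S0 = S0, sigma = sigma,
    provenance = list(nlm = nlm, smooth = if (bypass) 0 else smooth, fit = fit,
                      sigma = sigma, k_clamped = n_clamped,
                      package_version = as.character(utils::packageVersion("dkiphantom")))),
    class = "phantom_bundle")
  bundle
}

# Step 5: one-parameter LLS for beta = D'^2 K' / 6 in
# y = ln(S/S0) + b D' regressed on b^2 (per direction, vectorized).
refit_k_fixed_d <- function(ds, dm, Dp, fit) {
  sp <- split_volumes(ds, by = "direction")
  d3 <- dim(ds$signal)[1:3]
  nvox <- prod(d3)
  sig <- matrix(ds$signal, nrow = nvox)
  S0 <- rowMeans(sig[, sp$baseline, drop = FALSE])
  use <- as.vector((ds$brain_mask %||% array(TRUE, d3))) & S0 > 0
  Kp <- array(0, dim(Dp))
  # match tensor-fit direction order to split order (same construction)
  for (g in seq_along(sp$groups)) {
    vols <- sp$groups[[g]]
    b <- ds$scheme$bvals[vols]
    s <- t(sig[use, vols, drop = FALSE])
    s <- pmax(s, fit$min_signal_frac * rep(S0[use], each = length(vols)))
    Dg <- matrix(Dp, nrow = nvox)[use, g]
    y <- log(sweep(s, 2L, S0[use], "/")) + outer(b, Dg)
    w <- s^2
    x <- b^2 / 6
    beta <- colSums(w * x * y) / pmax(colSums(w * x * x), 1e-300)
    kv <- numeric(nvox)
    kv[use] <- ifelse(Dg > 0, beta / Dg^2, 0)
    Kp[, , , g] <- kv
  }
  Kp
}

# Forward synthesis of a 4D signal array from directional maps + baseline.
synth_from_directional <- function(dpp, S0, scheme, brain_mask) {
  d3 <- dim(S0)
  sig <- array(0, c(d3, scheme$n_volumes))
  sp <- split_volumes(scheme, by = "direction")
  for (v in sp$baseline) sig[, , , v] <- S0
  for (g in seq_along(sp$groups)) {
    # match group order to dpp direction order via the direction vectors
    dirg <- scheme$bvecs[sp$groups[[g]][1L], ]
    gi <- which.max(abs(dpp$directions %*% dirg))
    for (v in sp$groups[[g]]) {
      b <- scheme$bvals[v]
      sig[, , , v] <- predict_dki_signal(S0, b, dpp$D[, , , gi], dpp$K[, , , gi])
    }
  }
  sig  # background is 0 wherever S0 is 0
}

#' Resample a phantom onto a customized gradient scheme
#'
#' Evaluates the phantom's tensors along the directions of a new gradient
#' table and synthesizes DW volumes at its b-values, producing a dataset
#' with an acquisition design different from the one the phantom was built
#' from (e.g. a 3-b-value fast scheme). Negative tensor-implied K is clamped
#' to 0, matching the phantom synthesis rule, so resampling at the original
#' scheme reproduces the phantom exactly.
#'
#' @param bundle a `phantom_bundle` from [construct_phantom()].
#' @param new_scheme a [gradient_scheme()] containing at least one b = 0
#'   entry.
#' @return A [dwi_dataset()] under `new_scheme`.
#' @export
resample_scheme <- function(bundle, new_scheme) {
  stopifnot(inherits(bundle, "phantom_bundle"),
            inherits(new_scheme, "gradient_scheme"))
  if (!any(new_scheme$bvals == 0)) stop("new scheme must contain a b = 0 entry")
  sp <- split_volumes(new_scheme, by = "direction")
  dirs <- t(vapply(sp$groups, function(g) new_scheme$bvecs[g[1L], ], numeric(3)))
  dpp <- tensors_to_directional(bundle$tensors, dirs)
  dpp$K <- pmax(dpp$K, 0)
  mask <- bundle$noise_free$brain_mask %||% array(TRUE, dim(bundle$S0))
  sig <- synth_from_directional(dpp, bundle$S0, new_scheme, mask)
  dwi_dataset(sig, new_scheme, bundle$noise_free$voxel_size,
              bundle$noise_free$brain_mask, bundle$noise_free$background_mask)
}

#' Deterministic stream of noisy phantom realizations
#'
#' Lazily enumerates `n_realizations x length(sigmas)` Rician-corrupted
#' copies of the noise-free phantom. Per-realization seeds are derived
#' deterministically from `(base_seed, sigma index, realization index)`, so
#' the stream is reproducible and order-insensitive.
#'
#' @param bundle a `phantom_bundle`.
#' @param sigmas numeric vector of noise standard deviations.
#' @param n_realizations repetitions per noise level.
#' @param base_seed integer master seed.
#' @return A list with `n_total`, `grid` (data.frame of sigma/realization
#'   pairs in enumeration order), `realize(i_sigma, i_rep)` returning one
#'   noisy [dwi_dataset()], and `next_dataset()` stepping through the grid.
#' @export
make_noisy_realizations <- function(bundle, sigmas, n_realizations = 1L,
                                    base_seed = 1L) {
  stopifnot(inherits(bundle, "phantom_bundle"), n_realizations >= 1L)
  grid <- expand.grid(realization = seq_len(n_realizations),
                      sigma_index = seq_along(sigmas))[, 2:1]
  grid$sigma <- sigmas[grid$sigma_index]
  pos <- 0L
  realize <- function(i_sigma, i_rep) {
    seed <- derive_seed(base_seed, i_sigma, i_rep)
    noisy <- add_rician(bundle$noise_free$signal, sigmas[i_sigma], seed = seed)
    dwi_dataset(noisy, bundle$noise_free$scheme, bundle$noise_free$voxel_size,
                bundle$noise_free$brain_mask, bundle$noise_free$background_mask)
  }
  list(n_total = nrow(grid), grid = grid, realize = realize,
       next_dataset = function() {
         pos <<- pos + 1L
         if (pos > nrow(grid)) return(NULL)
         realize(grid$sigma_index[pos], grid$realization[pos])
       })
}

#' Wrap synthetic ground-truth tensors as a phantom bundle
#'
#' Builds a `phantom_bundle` directly from a known tensor field (no
#' denoising or re-fitting): the noise-free volumes are synthesized from the
#' tensors, so the bundle is tensor-consistent by construction. This is the
#' ground-truth object used when benchmarking denoisers on fully synthetic
#' data.
#'
#' @param tf a `tensor_field`.
#' @param S0 3D baseline map.
#' @param scheme a [gradient_scheme()].
#' @param voxel_size mm 3-vector.
#' @param brain_mask,background_mask optional 3D logical masks.
#' @return A `phantom_bundle`.
#' @export
phantom_from_tensors <- function(tf, S0, scheme, voxel_size = c(1, 1, 1),
                                 brain_mask = NULL, background_mask = NULL) {
  stopifnot(inherits(tf, "tensor_field"), inherits(scheme, "gradient_scheme"))
  sp <- split_volumes(scheme, by = "direction")
  if (length(sp$baseline) == 0L) stop("scheme must contain a b = 0 entry")
  dirs <- t(vapply(sp$groups, function(g) scheme$bvecs[g[1L], ], numeric(3)))
  dpp <- tensors_to_directional(tf, dirs)
  dpp$K <- pmax(dpp$K, 0)
  mask <- brain_mask %||% array(TRUE, dim(S0))
  sig <- synth_from_directional(dpp, S0, scheme, mask)
  structure(list(
    noise_free = dwi_dataset(sig, scheme, voxel_size, brain_mask, background_mask),
    tensors = tf, directional = dpp, S0 = S0, sigma = 0,
    provenance = list(source = "synthetic tensors",
                      package_version = as.character(utils::packageVersion("dkiphantom")))),
    class = "phantom_bundle")
}
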