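#' Mean squared error between a map and its noise-free reference
#'
#' `MSE = (1/N) sum_i (I_i - Q_i)^2` over the masked voxels (the brain
#' region, for brain data).
#'
#' @param I noise-free reference array.
#' @param Q estimated/denoised array of the same shape.
#' @param mask logical array selecting the scored voxels; `NULL` scores all.
#' @return Nonnegative scalar.
#' @export
mse_map <- function(I, Q, mask = NULL) {
  stopifnot(identical(dim(I), dim(Q)))
  mask <- mask %||% array(TRUE, dim(I))
  if (!any(mask)) stop("empty mask")
  mean((I[mask] - Q[mask])^2)
}

#' Absolute bias of an estimator across repeated realizations
#'
#' The systematic error component: the per-voxel mean over repetitions of
#' the estimate is compared with the reference, and the absolute deviations
#' are averaged over voxels, `Bias = (1/N) sum_i | mean_reps(Q_i) - I_i |`.
#' With `per_rep = TRUE` the single-realization variant is returned instead:
#' the mean over repetitions of `(1/N) sum_i |Q_i - I_i|` (useful as a
#' sensitivity check; it also contains the random error).
#'
#' @param I noise-free reference array.
#' @param Q_reps list of estimate arrays, one per repetition (length M >= 1).
#' @param mask logical array selecting the scored voxels.
#' @param per_rep compute the per-realization variant (see above).
#' @return Nonnegative scalar.
#' @export
bias_map <- function(I, Q_reps, mask = NULL, per_rep = FALSE) {
  if (!is.list(Q_reps)) Q_reps <- list(Q_reps)
  if (length(Q_reps) == 0L) stop("empty repetition list")
  mask <- mask %||% array(TRUE, dim(I))
  if (!any(mask)) stop("empty mask")
  Iv <- I[mask]
  nv <- sum(mask)
  Qm <- matrix(vapply(Q_reps, function(q) q[mask], numeric(nv)), nrow = nv)
  if (per_rep) mean(colMeans(abs(Qm - Iv)))
  else mean(abs(rowMeans(Qm) - Iv))
}

#' Voxelwise standard deviation across repeated realizations
#'
#' The random error component: the per-voxel standard deviation of the
#' estimate across repetitions (population convention, divisor M), averaged
#' over the masked voxels.
#'
#' @param Q_reps list of estimate arrays, one per repetition (M >= 2).
#' @param mask logical array selecting the scored voxels.
#' @return Nonnegative scalar.
#' @export
std_across_reps <- function(Q_reps, mask = NULL) {
  if (!is.list(Q_reps) || length(Q_reps) < 2L)
    stop("need at least 2 repetitions")
  mask <- mask %||% array(TRUE, dim(Q_reps[[1L]]))
  if (!any(mask)) stop("empty mask")
  nv <- sum(mask)
  Qm <- matrix(vapply(Q_reps, function(q) q[mask], numeric(nv)), nrow = nv)
  mu <- rowMeans(Qm)
  mean(sqrt(rowMeans((Qm - mu)^2)))
}

#' Benchmark denoising filters on a phantom across noise levels
#'
#' The full Monte-Carlo harness: for every `(filter mode, sigma)` pair it
#' draws `n_reps` Rician realizations of the phantom (seeds derived from
#' `(seed, sigma index, realization index)`, so all modes see identical
#' noise), denoises them, fits MD and MK by direction averaging, and scores
#' three targets against the phantom ground truth:
#' \describe{
#'   \item{`dwi`}{the denoised DW volumes themselves, pooled over all
#'     nonzero-b volumes;}
#'   \item{`MD`, `MK`}{the parameter maps from the denoised data.}
#' }
#' Metrics are [mse_map()] (averaged over repetitions), [bias_map()] and
#' [std_across_reps()], all restricted to the brain mask. The ground-truth
#' MD/MK are the direction averages of the phantom's own tensor-consistent
#' directional maps.
#'
#' @param bundle a `phantom_bundle`.
#' @param modes character vector of filter modes (subset of
#'   `c("none", "nlm", "vnlm_b", "vnlm_d")`; `"none"` scores the raw noisy
#'   data).
#' @param sigmas numeric vector of Rician noise levels.
#' @param n_reps repetitions per noise level (>= 2 for Std).
#' @param seed master seed.
#' @param fit a [fit_options()].
#' @return A data.frame with columns `filter`, `sigma`, `target`, `mse`,
#'   `bias`, `std`, `n_reps`, `n_voxels`.
#' @export
evaluate_filters <- function(bundle, modes = c("nlm", "vnlm_b", "vnlm_d"),
                             sigmas = c(5, 10, 15, 20, 25), n_reps = 25L,
                             seed = 1L, fit = fit_options()) {
  stopifnot(inherits(bundle, "phantom_bundle"), n_reps >= 2L)
  modes <- match.arg(modes, c("none", "nlm", "vnlm_b", "vnlm_d"), several.ok = TRUE)
  ds0 <- bundle$noise_free
  mask <- ds0$brain_mask %||% array(TRUE, dim(bundle$S0))
  nvox <- sum(mask)
  dw_idx <- which(ds0$scheme$bvals > 0)
  truth <- mean_dki_maps(bundle$directional, only_valid = FALSE)
  rows <- list()
  for (mode in modes) {
    for (is in seq_along(sigmas)) {
      sg <- sigmas[is]
      dwi_mse <- numeric(n_reps)
      dwi_sum <- 0; dwi_sumsq <- 0
      md_reps <- vector("list", n_reps)
      mk_reps <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        noisy <- add_rician(ds0$signal, sg, seed = derive_seed(seed, is, r))
        nds <- dwi_dataset(noisy, ds0$scheme, ds0$voxel_size,
                           ds0$brain_mask, ds0$background_mask)
        den <- if (mode == "none") nds else denoise_dwi(nds, mode, sigma = sg)
        dv <- matrix(den$signal[, , , dw_idx], ncol = length(dw_idx))[mask, , drop = FALSE]
        iv <- matrix(ds0$signal[, , , dw_idx], ncol = length(dw_idx))[mask, , drop = FALSE]
        dwi_mse[r] <- mean((dv - iv)^2)
        dwi_sum <- dwi_sum + dv
        dwi_sumsq <- dwi_sumsq + dv^2
        dmr <- fit_dki_directions(den, fit)
        mm <- mean_dki_maps(dmr, only_valid = FALSE)
        md_reps[[r]] <- mm$MD
        mk_reps[[r]] <- mm$MK
      }
      iv <- matrix(ds0$signal[, , , dw_idx], ncol = length(dw_idx))[mask, , drop = FALSE]
      dwi_mean <- dwi_sum / n_reps
      dwi_var <- pmax(dwi_sumsq / n_reps - dwi_mean^2, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = mode, sigma = sg, target = "dwi",
        mse = mean(dwi_mse), bias = mean(abs(dwi_mean - iv)),
        std = mean(sqrt(dwi_var)), n_reps = n_reps, n_voxels = nvox)
      for (tg in c("MD", "MK")) {
        reps <- if (tg == "MD") md_reps else mk_reps
        ref <- if (tg == "MD") truth$MD else truth$MK
        rows[[length(rows) + 1L]] <- data.frame(
          filter = mode, sigma = sg, target = tg,
          mse = mean(vapply(reps, function(q) mse_map(ref, q, mask), numeric(1))),
          bias = bias_map(ref, reps, mask),
          std = std_across_reps(reps, mask),
          n_reps = n_reps, n_voxels = nvox)
      }
    }
  }
  do.call(rbind, rows)
}
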