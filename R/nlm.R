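#' Parameters of the non-local means filter family
#'
#' Defaults follow the settings established for 3D diffusion-weighted MRI
#' denoising: a 5x5x5-voxel search region (`search_radius = 2`, i.e. 125
#' candidate voxels), a 3x3x3 neighborhood window (`patch_radius = 1`),
#' Gaussian patch weighting with `rho = 1.0`, and a smoothing bandwidth
#' proportional to the noise standard deviation, `h = h_factor * sigma`.
#' The bandwidth multiple depends on the filter variant: 1.0 for plain NLM,
#' 0.8 for vector NLM grouped by b-value (VNLM-b), 1.2 for vector NLM
#' grouped by gradient direction (VNLM-d).
#'
#' @param mode filter variant the parameters are for: `"nlm"`, `"vnlm_b"`
#'   or `"vnlm_d"`; sets the default `h_factor` (1.0 / 0.8 / 1.2).
#' @param search_radius search-region half-width t, voxels (region is
#'   `(2t+1)^3`).
#' @param patch_radius neighborhood half-width f, voxels (window is
#'   `(2f+1)^3`); must satisfy `t >= f >= 0`.
#' @param rho standard deviation (voxels) of the Gaussian patch weights.
#' @param h_factor bandwidth as a multiple of sigma; `NULL` picks the
#'   mode default.
#' @param sigma noise standard deviation (intensity units), used both for
#'   `h` and for Rician bias subtraction.
#' @param rician_correction apply the Rician bias subtraction after
#'   filtering (see [rician_unbias()]).
#' @return An `nlm_params` list.
#' @export
nlm_params <- function(mode = c("nlm", "vnlm_b", "vnlm_d"),
                       search_radius = 2L, patch_radius = 1L, rho = 1.0,
                       h_factor = NULL, sigma = NULL,
                       rician_correction = TRUE) {
  mode <- match.arg(mode)
  if (is.null(h_factor))
    h_factor <- c(nlm = 1.0, vnlm_b = 0.8, vnlm_d = 1.2)[[mode]]
  stopifnot(search_radius >= patch_radius, patch_radius >= 0,
            rho > 0, h_factor > 0, is.null(sigma) || sigma >= 0)
  structure(list(mode = mode, search_radius = as.integer(search_radius),
                 patch_radius = as.integer(patch_radius), rho = rho,
                 h_factor = h_factor, sigma = sigma,
                 rician_correction = isTRUE(rician_correction)),
            class = "nlm_params")
}

# Gaussian patch weights over the (2f+1)^3 offsets, normalized to sum 1.
# Normalizing makes the patch distance a weighted *mean* squared difference,
# so that h scales with sigma independently of patch size.
patch_weights <- function(patch_radius, rho) {
  f <- patch_radius
  off <- seq(-f, f)
  g1 <- exp(-off^2 / (2 * rho^2))
  w <- outer(outer(g1, g1), g1)
  as.numeric(w / sum(w))
}

bandwidth <- function(p, sigma = NULL) {
  sigma <- sigma %||% p$sigma
  if (is.null(sigma)) stop("sigma is required (supply it in nlm_params or as an argument)")
  p$h_factor * sigma
}

#' Gaussian-weighted patch distance between two voxels
#'
#' The squared-difference distance driving the NLM weights: the Gaussian-
#' weighted mean squared difference between the `(2f+1)^3` neighborhoods of
#' voxels `i` and `j` (weights normalized to sum 1; mirror padding at the
#' volume boundary).
#'
#' @param vol 3D numeric array.
#' @param i,j integer 3-vectors, 1-based voxel indices.
#' @param p an [nlm_params()].
#' @return Nonnegative scalar distance (squared-intensity units).
#' @export
patch_distance <- function(vol, i, j, p = nlm_params()) {
  stopifnot(length(dim(vol)) == 3L, length(i) == 3L, length(j) == 3L)
  f <- p$patch_radius
  w <- array(patch_weights(f, p$rho), rep(2L * f + 1L, 3L))
  d <- dim(vol)
  grab <- function(c0) {
    ix <- reflect_index(seq(c0[1] - f, c0[1] + f), d[1])
    iy <- reflect_index(seq(c0[2] - f, c0[2] + f), d[2])
    iz <- reflect_index(seq(c0[3] - f, c0[3] + f), d[3])
    vol[ix, iy, iz, drop = FALSE]
  }
  sum(w * (grab(i) - grab(j))^2)
}

#' 3D non-local means filter
#'
#' Replaces each voxel with a weighted average of the voxels in its search
#' region; the weight of voxel `j` is `exp(-d(i, j) / h^2)` with `d` the
#' [patch_distance()], and the center voxel's own weight uses the minimum
#' distance found in its search region. Weights are normalized to sum 1, so
#' each output value is a convex combination of its search region (plus the
#' mirror-padded boundary voxels).
#'
#' @param vol 3D numeric array.
#' @param p an [nlm_params()] (its `sigma`, or the `sigma` argument, sets
#'   the bandwidth `h = h_factor * sigma`).
#' @param sigma optional noise standard deviation overriding `p$sigma`.
#' @param mask optional 3D logical processing mask; outside it the input is
#'   copied through.
#' @param second_moment average squared intensities (with the same
#'   magnitude-derived weights) and return the square root of the weighted
#'   second moment. This is the averaging domain in which the subsequent
#'   Rician bias subtraction of [rician_unbias()] is exact; the plain
#'   magnitude average (default) is the textbook NLM estimate.
#' @return Denoised 3D array. No Rician correction is applied here; see
#'   [rician_unbias()].
#' @export
nlm3d <- function(vol, p = nlm_params("nlm"), sigma = NULL, mask = NULL,
                  second_moment = FALSE) {
  stopifnot(length(dim(vol)) == 3L)
  if (length(vol) == 0L) stop("empty volume")
  h <- bandwidth(p, sigma)
  if (h <= 0) return(vol)
  d <- dim(vol)
  out <- vnlm_core_cpp(as.numeric(vol), c(d, 1L),
                       p$search_radius, p$patch_radius,
                       patch_weights(p$patch_radius, p$rho), h,
                       as.logical(mask %||% array(TRUE, d)),
                       avg_sq = second_moment)
  array(out, d)
}

#' Rician bias subtraction
#'
#' Removes the second-moment bias that Rician noise adds to magnitude
#' images: `sqrt(max(x^2 - 2 sigma^2, 0))` voxelwise. Applied to an
#' NLM-filtered image this yields the unbiased NLM (UNLM) estimate.
#'
#' @param vol numeric array (typically an NLM output).
#' @param sigma Rician noise standard deviation, `>= 0`.
#' @return Array of the same shape; `sigma = 0` is the identity.
#' @export
rician_unbias <- function(vol, sigma) {
  if (sigma < 0) stop("sigma must be nonnegative")
  array(sqrt(pmax(vol^2 - 2 * sigma^2, 0)), dim(vol) %||% length(vol))
}

#' Vector non-local means over aligned channels
#'
#' Denoises several aligned 3D volumes as one entity: a single weight field
#' is computed from the channel-averaged patch distance
#' `d_v(i, j) = (1/V) sum_v d(i, j; channel v)`, and every channel is
#' averaged with those shared weights. Channels are deliberately not
#' intensity-normalized: structural similarity, not intensity similarity,
#' drives the weights. When `p$rician_correction` is `TRUE` the Rician bias
#' is subtracted per channel afterwards.
#'
#' @param channels list of 3D arrays sharing one shape, or a 4D array
#'   (x, y, z, channel).
#' @param p an [nlm_params()].
#' @param sigma optional noise standard deviation overriding `p$sigma`.
#' @param mask optional 3D logical processing mask.
#' @param second_moment average squared intensities under the shared weights
#'   (see [nlm3d()]); defaults to `p$rician_correction`, so that the bias
#'   subtraction operates in its exact domain.
#' @return Same container type as the input (list of 3D arrays, or 4D
#'   array), denoised.
#' @export
vnlm <- function(channels, p = nlm_params("vnlm_d"), sigma = NULL, mask = NULL,
                 second_moment = p$rician_correction) {
  as_list <- is.list(channels)
  if (as_list) {
    shp <- dim(channels[[1L]])
    if (!all(vapply(channels, function(x) identical(dim(x), shp), logical(1))))
      stop("channel shape mismatch")
    arr <- array(unlist(channels, use.names = FALSE), c(shp, length(channels)))
  } else {
    arr <- channels
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    shp <- dim(arr)[1:3]
  }
  V <- dim(arr)[4]
  sig <- sigma %||% p$sigma
  h <- bandwidth(p, sig)
  if (h > 0) {
    out <- vnlm_core_cpp(as.numeric(arr), dim(arr),
                         p$search_radius, p$patch_radius,
                         patch_weights(p$patch_radius, p$rho), h,
                         as.logical(mask %||% array(TRUE, shp)),
                         avg_sq = second_moment)
    arr <- array(out, dim(arr))
  }
  if (p$rician_correction && !is.null(sig) && sig > 0)
    arr <- rician_unbias(arr, sig)
  if (as_list) lapply(seq_len(V), function(v) array(arr[, , , v], shp)) else arr
}

#' Denoise a diffusion dataset with the NLM filter family
#'
#' Applies one of the three filter variants to every volume of a dataset:
#' \describe{
#'   \item{`nlm`}{each volume denoised independently (3D NLM).}
#'   \item{`vnlm_b`}{volumes sharing a b-value denoised jointly as one
#'     vector image (one [vnlm()] call per nonzero b-value).}
#'   \item{`vnlm_d`}{volumes sharing a gradient direction (across b-values)
#'     denoised jointly (one [vnlm()] call per direction).}
#' }
#' Baseline (b = 0) volumes are excluded from the vector groups and denoised
#' individually in every mode. All variants end with Rician bias subtraction
#' unless `p$rician_correction` is `FALSE`. When `sigma` is neither given
#' nor present in `p`, it is estimated from the dataset's background mask
#' via [estimate_sigma()] on the first baseline volume.
#'
#' @param ds a [dwi_dataset()].
#' @param mode `"nlm"`, `"vnlm_b"` or `"vnlm_d"`.
#' @param p an [nlm_params()]; `NULL` builds mode defaults (h_factor
#'   1.0 / 0.8 / 1.2).
#' @param sigma optional noise standard deviation.
#' @param mask optional 3D logical processing mask (default: all voxels).
#' @return A denoised [dwi_dataset()] with the same scheme and masks.
#' @export
denoise_dwi <- function(ds, mode = c("nlm", "vnlm_b", "vnlm_d"),
                        p = NULL, sigma = NULL, mask = NULL) {
  stopifnot(inherits(ds, "dwi_dataset"))
  mode <- match.arg(mode)
  p <- p %||% nlm_params(mode)
  sigma <- sigma %||% p$sigma
  if (is.null(sigma)) {
    if (is.null(ds$background_mask))
      stop("sigma not given and no background_mask to estimate it from")
    b0 <- which(ds$scheme$bvals == 0)[1L]
    sigma <- estimate_sigma(ds$signal[, , , b0], ds$background_mask)
  }
  d <- dim(ds$signal)
  out <- ds$signal
  # baselines: individual 3D NLM + unbiasing in every mode
  pb <- nlm_params("nlm", search_radius = p$search_radius,
                   patch_radius = p$patch_radius, rho = p$rho,
                   rician_correction = p$rician_correction)
  sp <- split_volumes(ds, by = if (mode == "vnlm_b") "b_value" else "direction")
  for (v in sp$baseline) {
    den <- nlm3d(ds$signal[, , , v], pb, sigma = sigma, mask = mask,
                 second_moment = p$rician_correction)
    if (p$rician_correction && sigma > 0) den <- rician_unbias(den, sigma)
    out[, , , v] <- den
  }
  if (mode == "nlm") {
    for (v in unlist(sp$groups, use.names = FALSE)) {
      den <- nlm3d(ds$signal[, , , v], p, sigma = sigma, mask = mask,
                   second_moment = p$rician_correction)
      if (p$rician_correction && sigma > 0) den <- rician_unbias(den, sigma)
      out[, , , v] <- den
    }
  } else {
    for (grp in sp$groups) {
      arr <- ds$signal[, , , grp, drop = FALSE]
      dim(arr) <- c(d[1:3], length(grp))
      den <- vnlm(arr, p, sigma = sigma, mask = mask)
      out[, , , grp] <- den
    }
  }
  dwi_dataset(out, ds$scheme, ds$voxel_size, ds$brain_mask, ds$background_mask)
}
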