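#' Add Rician noise to a magnitude image
#'
#' Corrupts a nonnegative signal the way magnitude reconstruction corrupts
#' complex MR data: `In = sqrt((I + n1)^2 + n2^2)` with `n1, n2` independent
#' `N(0, sigma^2)` draws, fresh per voxel and volume. A fixed `sigma` is
#' used for all volumes (spatially and across-volume iid noise).
#'
#' @param vol nonnegative numeric array (3D or 4D).
#' @param sigma Gaussian standard deviation of each quadrature channel,
#'   `>= 0` (intensity units).
#' @param seed optional integer; when given, the draw is reproducible.
#' @return Array of the same shape, nonnegative; `sigma = 0` returns the
#'   input unchanged.
#' @examples
#' x <- add_rician(array(100, c(10, 10, 10)), sigma = 10, seed = 1)
#' mean(x^2)  # approx 100^2 + 2 * 10^2
#' @export
add_rician <- function(vol, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(vol)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  n <- length(vol)
  n1 <- stats::rnorm(n, 0, sigma)
  n2 <- stats::rnorm(n, 0, sigma)
  array(sqrt((as.numeric(vol) + n1)^2 + n2^2), dim(vol) %||% n)
}

#' Estimate the Rician noise level from a background region
#'
#' In a signal-free background the magnitude image is pure Rician (Rayleigh)
#' noise with second moment `2 sigma^2`, so
#' `sigma = sqrt(mean(background^2) / 2)`.
#'
#' @param vol numeric array (a single volume; conventionally the baseline,
#'   which has the highest SNR).
#' @param background_mask 3D logical array marking pure-noise voxels;
#'   must select at least one voxel.
#' @return Estimated sigma (intensity units).
#' @export
estimate_sigma <- function(vol, background_mask) {
  stopifnot(is.logical(background_mask))
  vals <- vol[background_mask]
  if (length(vals) == 0L) stop("empty background mask")
  sqrt(mean(vals^2) / 2)
}

#' Derive a background mask from the brain mask
#'
#' Takes the complement of the morphologically dilated brain mask (removing
#' the partial-volume rim) and intersects it with the border shell of the
#' image, yielding voxels safely outside any tissue.
#'
#' @param ds a [dwi_dataset()] with a `brain_mask`.
#' @param dilate_radius half-width (voxels) of the cubic dilation applied to
#'   the brain mask before taking the complement.
#' @param shell_width thickness (voxels) of the image-border shell retained.
#' @return 3D logical background mask.
#' @export
auto_background <- function(ds, dilate_radius = 3L, shell_width = 4L) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (is.null(ds$brain_mask)) stop("dataset has no brain_mask")
  d <- dim(ds$brain_mask)
  dil <- dilate_mask3d(ds$brain_mask, dilate_radius)
  shell <- array(TRUE, d)
  if (all(d > 2L * shell_width))
    shell[(shell_width + 1L):(d[1] - shell_width),
          (shell_width + 1L):(d[2] - shell_width),
          (shell_width + 1L):(d[3] - shell_width)] <- FALSE
  bg <- !dil & shell
  if (!any(bg)) stop("no background voxels: mask covers the entire volume")
  bg
}
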