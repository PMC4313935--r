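#' Diffusion-weighted dataset
#'
#' Binds a 4D signal array (x, y, z, volume) to its [gradient_scheme()],
#' voxel geometry and optional brain / background masks. Signal values must
#' be finite and nonnegative (magnitude images); the fourth dimension must
#' match the scheme's volume count; brain and background masks, when both
#' present, must be disjoint.
#'
#' @param signal 4D numeric array, dimensions (x, y, z, volume).
#' @param scheme a [gradient_scheme()].
#' @param voxel_size numeric 3-vector, voxel edge lengths in mm.
#' @param brain_mask optional 3D logical array marking brain voxels.
#' @param background_mask optional 3D logical array marking pure-noise
#'   background voxels.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, scheme, voxel_size = c(1, 1, 1),
                        brain_mask = NULL, background_mask = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  d <- dim(signal)
  if (length(d) == 3L) { dim(signal) <- c(d, 1L); d <- dim(signal) }
  if (length(d) != 4L) stop("signal must be a 4D array (x, y, z, volume)")
  if (d[4] != scheme$n_volumes)
    stop(sprintf("volume-count mismatch: image has %d volumes, scheme has %d",
                 d[4], scheme$n_volumes))
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  if (any(signal < 0)) stop("signal contains negative values")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  chk_mask <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- array(as.logical(m), dim = d[1:3])
    if (any(is.na(m))) stop(nm, " contains NA")
    m
  }
  brain_mask <- chk_mask(brain_mask, "brain_mask")
  background_mask <- chk_mask(background_mask, "background_mask")
  if (!is.null(brain_mask) && !is.null(background_mask) &&
      any(brain_mask & background_mask))
    stop("brain_mask and background_mask overlap")
  structure(list(signal = signal, scheme = scheme, voxel_size = voxel_size,
                 brain_mask = brain_mask, background_mask = background_mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_dataset: %dx%dx%d voxels (%.3gx%.3gx%.3g mm), %d volumes\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], d[4]))
  print(x$scheme)
  invisible(x)
}

# -- FSL-dialect gradient tables ---------------------------------------------

read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- scan(bvec_path, what = numeric(), quiet = TRUE)
  if (length(bv) != 3L * length(bvals))
    stop(sprintf("bvec has %d values; expected 3 x %d", length(bv), length(bvals)))
  bvecs <- matrix(bv, nrow = 3L, byrow = TRUE)  # 3 rows: x, y, z components
  gradient_scheme(bvals, t(bvecs))
}

write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  bm <- t(scheme$bvecs)
  writeLines(apply(bm, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read a diffusion dataset from NIfTI + FSL bval/bvec files
#'
#' Loads a 4D NIfTI volume and its whitespace-delimited FSL-style gradient
#' tables (one row of b-values; three rows of x/y/z direction components),
#' validates their consistency and returns a [dwi_dataset()]. Direction
#' vectors with `b > 0` are renormalized to unit length. Processing is
#' carried out in voxel space; the voxel size is taken from the NIfTI header
#' and used only for mm-parameterized kernels.
#'
#' @param nifti_path path to the 4D image (.nii or .nii.gz).
#' @param bval_path,bvec_path paths to the gradient tables.
#' @param brain_mask_path,background_mask_path optional 3D mask volumes.
#' @param average_b0 if `TRUE`, all baseline volumes are averaged into a
#'   single high-SNR baseline on load (as done when many baseline repeats
#'   are acquired).
#' @return A [dwi_dataset()].
#' @export
read_dwi_dataset <- function(nifti_path, bval_path, bvec_path,
                             brain_mask_path = NULL,
                             background_mask_path = NULL,
                             average_b0 = FALSE) {
  img <- RNifti::readNifti(nifti_path)
  scheme <- read_bval_bvec(bval_path, bvec_path)
  sig <- array(as.numeric(img), dim = dim(img))
  if (length(dim(sig)) == 3L) dim(sig) <- c(dim(sig), 1L)
  vx <- RNifti::pixdim(img)[1:3]
  rd_mask <- function(p) {
    if (is.null(p)) return(NULL)
    m <- RNifti::readNifti(p)
    array(as.numeric(m) > 0, dim = dim(m)[1:3])
  }
  ds <- dwi_dataset(sig, scheme, voxel_size = vx,
                    brain_mask = rd_mask(brain_mask_path),
                    background_mask = rd_mask(background_mask_path))
  if (average_b0) ds <- average_baselines(ds)
  ds
}

#' Collapse multiple baseline volumes into one averaged baseline
#'
#' @param ds a [dwi_dataset()].
#' @return A [dwi_dataset()] whose first volume is the mean of all `b = 0`
#'   volumes, followed by the DW volumes in their original order.
#' @export
average_baselines <- function(ds) {
  stopifnot(inherits(ds, "dwi_dataset"))
  b0 <- which(ds$scheme$bvals == 0)
  if (length(b0) <= 1L) return(ds)
  dw <- which(ds$scheme$bvals > 0)
  d <- dim(ds$signal)
  mean_b0 <- array(rowMeans(matrix(ds$signal[, , , b0], ncol = length(b0))), d[1:3])
  sig <- array(0, c(d[1:3], 1L + length(dw)))
  sig[, , , 1L] <- mean_b0
  sig[, , , -1L] <- ds$signal[, , , dw]
  sch <- gradient_scheme(c(0, ds$scheme$bvals[dw]),
                         rbind(c(0, 0, 0), ds$scheme$bvecs[dw, , drop = FALSE]))
  dwi_dataset(sig, sch, ds$voxel_size, ds$brain_mask, ds$background_mask)
}

#' Write a diffusion dataset as NIfTI + FSL bval/bvec files
#'
#' Writes `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec` and, when masks
#' are present, `<prefix>_brain_mask.nii.gz` / `<prefix>_background_mask.nii.gz`.
#' The signal is stored at double precision so that
#' [read_dwi_dataset()] round-trips it bit-identically; directions round-trip
#' within 1e-6.
#'
#' @param ds a [dwi_dataset()].
#' @param out_prefix output path prefix.
#' @return Invisibly, the named character vector of files written.
#' @export
write_dwi_dataset <- function(ds, out_prefix) {
  stopifnot(inherits(ds, "dwi_dataset"))
  paths <- c(image = paste0(out_prefix, ".nii.gz"),
             bval = paste0(out_prefix, ".bval"),
             bvec = paste0(out_prefix, ".bvec"))
  img <- RNifti::asNifti(ds$signal)
  RNifti::pixdim(img) <- c(ds$voxel_size, 1)
  RNifti::writeNifti(img, paths[["image"]], datatype = "double")
  write_bval_bvec(ds$scheme, paths[["bval"]], paths[["bvec"]])
  wr_mask <- function(m, nm) {
    p <- paste0(out_prefix, "_", nm, ".nii.gz")
    mi <- RNifti::asNifti(array(as.integer(m), dim(m)))
    RNifti::pixdim(mi) <- ds$voxel_size
    RNifti::writeNifti(mi, p, datatype = "uint8")
    p
  }
  if (!is.null(ds$brain_mask))
    paths <- c(paths, brain_mask = wr_mask(ds$brain_mask, "brain_mask"))
  if (!is.null(ds$background_mask))
    paths <- c(paths, background_mask = wr_mask(ds$background_mask, "background_mask"))
  invisible(paths)
}
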