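#' Gradient scheme: b-values and gradient directions per volume
#'
#' A `gradient_scheme` describes a diffusion acquisition design: one b-value
#' (s/mm^2) and one unit gradient direction per volume. Directions paired with
#' `b > 0` are renormalized to unit length; the zero vector is only accepted
#' for baseline (`b = 0`) volumes.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix of gradient directions, `n_volumes x 3`
#'   (rows are direction vectors) or `3 x n_volumes`.
#' @return An object of class `gradient_scheme` with elements `bvals`
#'   (rounded to the nearest 1 s/mm^2), `bvecs` (`n x 3`, unit rows where
#'   `b > 0`) and `n_volumes`.
#' @examples
#' sch <- gradient_scheme(c(0, 1000, 1000), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' sch$n_volumes
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  if (any(!is.finite(bvals))) stop("non-finite b-values")
  if (any(bvals < 0)) stop("negative b-values are not allowed")
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 components per volume")
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("volume-count mismatch: %d b-values vs %d directions",
                 length(bvals), nrow(bvecs)))
  if (any(!is.finite(bvecs))) stop("non-finite gradient components")
  # scanner tables are integer-valued; round for robust grouping
  bvals <- round(bvals)
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(dw & nrm < 1e-12))
    stop("zero gradient vector paired with b > 0")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = unname(bvecs),
                 n_volumes = length(bvals)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  ub <- sort(unique(x$bvals))
  cat(sprintf("gradient_scheme: %d volumes, b-values {%s} s/mm^2\n",
              x$n_volumes, paste(ub, collapse = ", ")))
  invisible(x)
}

#' Partition DW volumes by shared b-value or shared gradient direction
#'
#' Groups the nonzero-b volumes of a scheme either by b-value (volumes of the
#' same diffusion weighting across directions) or by gradient direction
#' (volumes along one direction across b-values). These are the two natural
#' vector groupings for jointly denoising a kurtosis acquisition. Baseline
#' (`b = 0`) volumes always form their own group. Direction identity is
#' sign-invariant (antipodal vectors are identified, since the diffusion
#' signal is antipodally symmetric): two directions match when
#' `|dot| >= 1 - 1e-4`.
#'
#' @param scheme a [gradient_scheme()] (or a `dwi_dataset`, whose scheme is
#'   used).
#' @param by `"b_value"` or `"direction"`.
#' @return A list with `baseline` (integer indices of b = 0 volumes) and
#'   `groups` (named list of integer index vectors partitioning the nonzero-b
#'   volumes).
#' @export
split_volumes <- function(scheme, by = c("b_value", "direction")) {
  if (inherits(scheme, "dwi_dataset")) scheme <- scheme$scheme
  stopifnot(inherits(scheme, "gradient_scheme"))
  by <- match.arg(by)
  idx <- seq_len(scheme$n_volumes)
  b0 <- idx[scheme$bvals == 0]
  dw <- idx[scheme$bvals > 0]
  if (length(dw) == 0L)
    return(list(baseline = b0, groups = list()))
  if (by == "b_value") {
    groups <- split(dw, scheme$bvals[dw])
    names(groups) <- paste0("b", names(groups))
  } else {
    vecs <- scheme$bvecs[dw, , drop = FALSE]
    gid <- integer(length(dw))
    reps <- matrix(numeric(0), 0, 3)
    for (k in seq_along(dw)) {
      v <- vecs[k, ]
      hit <- 0L
      if (nrow(reps) > 0L) {
        dots <- abs(reps %*% v)
        w <- which(dots >= 1 - 1e-4)
        if (length(w)) hit <- w[1L]
      }
      if (hit == 0L) {
        reps <- rbind(reps, v)
        hit <- nrow(reps)
      }
      gid[k] <- hit
    }
    groups <- split(dw, gid)
    names(groups) <- paste0("dir", names(groups))
  }
  list(baseline = b0, groups = groups)
}
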