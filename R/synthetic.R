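#' Deterministic multi-shell gradient scheme
#'
#' Builds a DKI-style acquisition design: one baseline volume plus one
#' volume for every (direction, nonzero b-value) pair. Directions are
#' deterministic, approximately uniform unit vectors from the spherical
#' Fibonacci lattice, so the same inputs always yield the same scheme.
#'
#' @param n_directions number of gradient directions (>= 6, the minimum for
#'   a diffusion tensor).
#' @param bvals b-values in s/mm^2; any 0 entries collapse into the single
#'   leading baseline volume.
#' @return A [gradient_scheme()] with `1 + n_directions * n_nonzero_b`
#'   volumes, ordered baseline first, then direction-major.
#' @examples
#' make_gradient_scheme(30, c(0, 500, 1000, 1500, 2000, 2500))$n_volumes  # 151
#' @export
make_gradient_scheme <- function(n_directions, bvals) {
  if (n_directions < 6) stop("need at least 6 directions")
  bnz <- sort(unique(round(bvals[bvals > 0])))
  dirs <- fibonacci_sphere(n_directions)
  b <- c(0, rep(bnz, times = n_directions))
  v <- rbind(c(0, 0, 0),
             dirs[rep(seq_len(n_directions), each = length(bnz)), , drop = FALSE])
  gradient_scheme(b, v)
}

# Isotropic fully symmetric rank-4 tensor whose quartic form equals w for
# every unit direction; 15-element unique order as in kt_design().
isotropic_kurtosis_tensor <- function(w) {
  c(w, w, w, rep(0, 6), rep(w / 3, 3), rep(0, 3))
}

# Symmetric rank-2 tensor (xx, yy, zz, xy, xz, yz) of a prolate diffusion
# profile with principal axis `axis`.
prolate_tensor <- function(axis, axial, radial) {
  n <- axis / sqrt(sum(axis^2))
  M <- radial * diag(3) + (axial - radial) * tcrossprod(n)
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

#' Tissue compartment specification for synthetic phantoms
#'
#' Describes one region of a synthetic phantom in voxel coordinates: its
#' shape, its diffusion tensor (or isotropic diffusivity), its kurtosis
#' tensor (or a scalar shorthand `w`, meaning the isotropic rank-4 tensor
#' whose directional kurtosis is `w * MD^2 / D(n)^2`), and its baseline
#' intensity. Later regions overwrite earlier ones.
#'
#' @param shape `"ellipsoid"`, `"box"` or `"annulus"` (a cylindrical annulus
#'   in the xy plane).
#' @param center voxel-coordinate center (3-vector).
#' @param size shape parameters, voxels: ellipsoid semi-axes (3-vector); box
#'   half-widths (3-vector); annulus `c(r_inner, r_outer, half_height)`.
#' @param D isotropic diffusivity (mm^2/s) — ignored when `Dt` is given.
#' @param Dt 6-element diffusion tensor `(xx, yy, zz, xy, xz, yz)`, or the
#'   string `"tangential"` for a prolate tensor whose principal axis rotates
#'   tangentially around `center` (fiber-like texture; uses `axial` and
#'   `radial`).
#' @param axial,radial eigenvalues (mm^2/s) for `Dt = "tangential"`.
#' @param K scalar kurtosis shorthand `w` (isotropic rank-4 tensor).
#' @param Wt optional explicit 15-element kurtosis tensor overriding `K`.
#' @param S0 baseline intensity of the region.
#' @return A `region_spec` list.
#' @export
region_spec <- function(shape = c("ellipsoid", "box", "annulus"),
                        center, size, D = NULL, Dt = NULL,
                        axial = 1.7e-3, radial = 0.3e-3,
                        K = 0, Wt = NULL, S0 = 100) {
  shape <- match.arg(shape)
  stopifnot(S0 > 0, length(center) == 3L, length(size) == 3L)
  if (is.null(Dt) && is.null(D)) stop("give D or Dt")
  structure(list(shape = shape, center = center, size = size, D = D, Dt = Dt,
                 axial = axial, radial = radial, K = K, Wt = Wt, S0 = S0),
            class = "region_spec")
}

# Default three-compartment layout for a grid: a fiber-like white-matter
# annulus with tangentially rotating prolate tensors, a gray-matter-like
# ellipsoid, and a CSF-like core, inside a zero-signal background.
default_phantom_regions <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  rxy <- min(grid_shape[1:2]) / 2
  rz <- grid_shape[3] / 2
  list(
    # GM-like: isotropic, moderate diffusivity, high kurtosis
    region_spec("ellipsoid", c0, c(0.82 * rxy, 0.82 * rxy, 0.80 * rz),
                D = 0.9e-3, K = 0.9, S0 = 320),
    # WM-like: prolate, tangentially rotating fibers
    region_spec("annulus", c0, c(0.28 * rxy, 0.60 * rxy, 0.55 * rz),
                Dt = "tangential", axial = 1.7e-3, radial = 0.3e-3,
                K = 0.3, S0 = 270),
    # CSF-like core: fast isotropic diffusion, near-Gaussian
    region_spec("ellipsoid", c0, c(0.20 * rxy, 0.20 * rxy, 0.40 * rz),
                D = 3.0e-3, K = 0.1, S0 = 400)
  )
}

#' Synthetic tensor-defined phantom
#'
#' Generates a piecewise-smooth ground-truth tensor field with tissue-like
#' compartments on a regular grid. The default layout (32 x 32 x 12 voxels
#' of 2 x 2 x 3 mm) contains a white-matter-like annulus of prolate tensors
#' (axial 1.7e-3, radial 0.3e-3 mm^2/s) whose fiber orientation rotates
#' smoothly around the ring — giving the patch-similarity texture that
#' patch-based filters exploit — a gray-matter-like compartment (isotropic
#' 0.9e-3 mm^2/s, kurtosis 0.9), a CSF-like core (3.0e-3 mm^2/s, kurtosis
#' 0.1), and a zero-signal background shell.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param voxel_size mm 3-vector.
#' @param regions list of [region_spec()]s painted in order (later wins);
#'   `NULL` uses the default layout above.
#' @return A list with `tensors` (`tensor_field`), `S0` (3D map),
#'   `brain_mask`, `background_mask`, `voxel_size`, and `S0_reference` (the
#'   nominal baseline intensity used to express noise levels as fractions
#'   of S0).
#' @export
make_tensor_phantom <- function(grid_shape = c(32L, 32L, 12L),
                                voxel_size = c(2, 2, 3),
                                regions = NULL) {
  grid_shape <- as.integer(grid_shape)
  regions <- regions %||% default_phantom_regions(grid_shape)
  d3 <- grid_shape
  nvox <- prod(d3)
  co <- as.matrix(expand.grid(x = seq_len(d3[1]), y = seq_len(d3[2]),
                              z = seq_len(d3[3])))
  Dt <- matrix(0, nvox, 6)
  Wt <- matrix(0, nvox, 15)
  S0 <- numeric(nvox)
  inside_any <- logical(nvox)
  for (rg in regions) {
    rel <- sweep(co, 2L, rg$center)
    inside <- switch(rg$shape,
      ellipsoid = rowSums(sweep(rel, 2L, rg$size, "/")^2) <= 1,
      box = apply(abs(sweep(rel, 2L, rg$size, "/")) <= 1, 1L, all),
      annulus = {
        r <- sqrt(rel[, 1]^2 + rel[, 2]^2)
        r >= rg$size[1] & r <= rg$size[2] & abs(rel[, 3]) <= rg$size[3]
      })
    if (!any(inside)) next
    if (identical(rg$Dt, "tangential")) {
      # fiber axis tangential to the ring, with a gentle out-of-plane pitch
      # varying along z so orientation changes smoothly in all 3 axes
      rel_in <- rel[inside, , drop = FALSE]
      theta <- atan2(rel_in[, 2], rel_in[, 1])
      pitch <- 0.3 * rel_in[, 3] / max(rg$size[3], 1)
      ax <- cbind(-sin(theta) * cos(pitch), cos(theta) * cos(pitch), sin(pitch))
      idx <- which(inside)
      for (ii in seq_along(idx))
        Dt[idx[ii], ] <- prolate_tensor(ax[ii, ], rg$axial, rg$radial)
    } else if (!is.null(rg$Dt)) {
      Dt[inside, ] <- matrix(rg$Dt, sum(inside), 6, byrow = TRUE)
    } else {
      Dt[inside, ] <- matrix(c(rg$D, rg$D, rg$D, 0, 0, 0), sum(inside), 6,
                             byrow = TRUE)
    }
    wt <- rg$Wt %||% isotropic_kurtosis_tensor(rg$K)
    Wt[inside, ] <- matrix(wt, sum(inside), 15, byrow = TRUE)
    S0[inside] <- rg$S0
    inside_any <- inside_any | inside
  }
  # validity: positive semidefinite diffusion tensors inside the brain
  MD <- rowSums(Dt[, 1:3, drop = FALSE]) / 3
  brain <- inside_any & S0 > 0
  tf <- structure(list(Dt = array(Dt, c(d3, 6L)), Wt = array(Wt, c(d3, 15L)),
                       MD = array(MD, d3),
                       MK = array(numeric(nvox), d3),
                       valid = array(brain, d3)),
                  class = "tensor_field")
  # numerical MK over a fixed 30-direction set
  mk_dirs <- fibonacci_sphere(30)
  tf$MK <- mean_dki_maps(tensors_to_directional(tf, mk_dirs), only_valid = FALSE)$MK
  list(tensors = tf, S0 = array(S0, d3),
       brain_mask = array(brain, d3),
       background_mask = array(!inside_any, d3),
       voxel_size = voxel_size,
       S0_reference = 300)
}

#' Forward-synthesize a diffusion dataset from ground-truth tensors
#'
#' Evaluates the tensor field along the scheme's directions and applies the
#' kurtosis signal model at each b-value; baseline volumes equal the S0 map.
#'
#' @param tf a `tensor_field`.
#' @param S0 3D baseline map (0 outside the object).
#' @param scheme a [gradient_scheme()] with a baseline entry.
#' @param voxel_size mm 3-vector.
#' @param brain_mask,background_mask optional masks carried into the result.
#' @return A noise-free [dwi_dataset()].
#' @export
synthesize_dwi <- function(tf, S0, scheme, voxel_size = c(1, 1, 1),
                           brain_mask = NULL, background_mask = NULL) {
  bundle <- phantom_from_tensors(tf, S0, scheme, voxel_size,
                                 brain_mask, background_mask)
  bundle$noise_free
}

#' Default synthetic benchmark phantom
#'
#' One-call constructor of the full ground-truth bundle used in the
#' denoiser benchmark: the default [make_tensor_phantom()] layout sampled
#' under a given acquisition design.
#'
#' @param n_directions gradient directions (default 12).
#' @param bvals b-values, s/mm^2 (default `c(0, 1000, 1500, 2000, 2500)`).
#' @param grid_shape,voxel_size grid geometry.
#' @return A `phantom_bundle` (see [phantom_from_tensors()]), with the
#'   phantom's `S0_reference` attached as attribute `"S0_reference"`.
#' @export
default_phantom_bundle <- function(n_directions = 12L,
                                   bvals = c(0, 1000, 1500, 2000, 2500),
                                   grid_shape = c(32L, 32L, 12L),
                                   voxel_size = c(2, 2, 3)) {
  ph <- make_tensor_phantom(grid_shape, voxel_size)
  sch <- make_gradient_scheme(n_directions, bvals)
  bundle <- phantom_from_tensors(ph$tensors, ph$S0, sch, ph$voxel_size,
                                 ph$brain_mask, ph$background_mask)
  attr(bundle, "S0_reference") <- ph$S0_reference
  bundle
}
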