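#' Forward diffusion kurtosis signal model
#'
#' Predicts the diffusion-weighted magnitude signal along one gradient
#' direction under the kurtosis extension of the mono-exponential decay:
#' \deqn{S(b) = S_0 \exp(-b D + b^2 D^2 K / 6)}
#' where `D` is the apparent diffusion coefficient (mm^2/s) along the
#' direction and `K` the (dimensionless) apparent kurtosis. `K = 0` reduces
#' to the mono-exponential diffusion-tensor decay.
#'
#' @param S0 baseline signal intensity (b = 0), nonnegative.
#' @param b b-value (s/mm^2), nonnegative.
#' @param D apparent diffusion coefficient (mm^2/s), nonnegative.
#' @param K apparent kurtosis (dimensionless).
#' @return Predicted signal intensity; vectorized over all arguments.
#' @examples
#' predict_dki_signal(100, 1000, 1e-3, 0)    # mono-exponential: 100 * exp(-1)
#' predict_dki_signal(100, 2500, 1e-3, 1)
#' @export
predict_dki_signal <- function(S0, b, D, K = 0) {
  S0 * exp(-b * D + b^2 * D^2 * K / 6)
}

#' Fitting policy for DKI parameter estimation
#'
#' @param s0_policy how the baseline is obtained: `"measured_baseline"` uses
#'   the (averaged) acquired b = 0 volume (appropriate when a high-SNR
#'   baseline is available); fitting S0 is deliberately not offered.
#' @param k_bounds optional length-2 numeric `(lo, hi)`: kurtosis estimates
#'   are clamped into this interval. `NULL` (default) leaves K unconstrained
#'   so that negative-kurtosis "black hole" voxels remain observable.
#' @param min_signal_frac positive clamp floor, as a fraction of S0: signals
#'   `<= 0` are replaced by `min_signal_frac * S0` before the log transform
#'   and the voxel is flagged.
#' @return A `fit_options` list.
#' @export
fit_options <- function(s0_policy = "measured_baseline", k_bounds = NULL,
                        min_signal_frac = 1e-6) {
  stopifnot(identical(s0_policy, "measured_baseline"),
            min_signal_frac > 0)
  if (!is.null(k_bounds)) stopifnot(length(k_bounds) == 2L, k_bounds[1] <= k_bounds[2])
  structure(list(s0_policy = s0_policy, k_bounds = k_bounds,
                 min_signal_frac = min_signal_frac),
            class = "fit_options")
}

# Weighted linear least squares for the log-linearized kurtosis decay.
# y = ln(S/S0) = -b D + (b^2/6) beta with beta = D^2 K; weights = S^2
# (the standard first-order variance correction for log-transformed signal).
# Solved per voxel by Gram-Schmidt orthogonalization of the weighted design
# (condition number of the design, not its square), vectorized over voxels.
# ymat: nb x nvox matrix of log-ratios; w: nb x nvox weights; b: nb b-values.
# Returns list(D, beta, ok) of length-nvox vectors.
wls_dki <- function(ymat, w, b) {
  sw <- sqrt(w)
  u1 <- sw * (-b)          # nb x nvox weighted regressor columns
  u2 <- sw * (b^2 / 6)
  yw <- sw * ymat
  r11 <- sqrt(colSums(u1^2))
  ok <- r11 > 0
  q1 <- sweep(u1, 2L, pmax(r11, 1e-300), "/")
  r12 <- colSums(q1 * u2)
  v <- u2 - sweep(q1, 2L, r12, "*")
  r22 <- sqrt(colSums(v^2))
  ok <- ok & r22 > 1e-10 * sqrt(colSums(u2^2))
  q2 <- sweep(v, 2L, pmax(r22, 1e-300), "/")
  solve_qr <- function(rhs) {
    beta <- colSums(q2 * rhs) / pmax(r22, 1e-300)
    D <- (colSums(q1 * rhs) - r12 * beta) / pmax(r11, 1e-300)
    list(D = D, beta = beta)
  }
  th <- solve_qr(yw)
  # one step of iterative refinement: the squared-signal weights can span
  # ~20 orders of magnitude at extreme (D, K), costing digits in the solve
  res <- yw - (sweep(u1, 2L, th$D, "*") + sweep(u2, 2L, th$beta, "*"))
  corr <- solve_qr(res)
  list(D = ifelse(ok, th$D + corr$D, 0),
       beta = ifelse(ok, th$beta + corr$beta, 0), ok = ok)
}

#' Estimate directional diffusion and kurtosis from one decay curve
#'
#' Fits `(D, K)` for a single gradient direction from signals measured at
#' several b-values (including at least one baseline), by weighted linear
#' least squares on the log-linearized model
#' `ln(S/S0) = -b D + (b^2/6) (D^2 K)` with weights `S^2`. The baseline S0
#' is the mean of the `b = 0` measurements (not fitted). At least 3 distinct
#' b-values including b = 0 are required (two unknowns plus the baseline).
#'
#' @param signals numeric vector of signal intensities, one per b-value.
#' @param bvals numeric vector of b-values (s/mm^2), same length.
#' @param opts a [fit_options()].
#' @return A list with `D` (mm^2/s), `K` (dimensionless) and `valid`
#'   (`FALSE` when `D <= 0` or any signal required clamping).
#' @examples
#' b <- c(0, 500, 1000, 1500, 2000, 2500)
#' s <- predict_dki_signal(100, b, 1.2e-3, 0.8)
#' fit_dki_direction(s, b)
#' @export
fit_dki_direction <- function(signals, bvals, opts = fit_options()) {
  stopifnot(length(signals) == length(bvals))
  bvals <- round(as.numeric(bvals))
  if (length(unique(bvals)) < 3L || !any(bvals == 0))
    stop("need at least 3 distinct b-values including b = 0")
  if (all(signals <= 0)) stop("all-zero (or negative) signals: nothing to fit")
  S0 <- mean(signals[bvals == 0])
  dw <- bvals > 0
  s <- signals[dw]
  clamped <- any(s <= 0)
  s <- pmax(s, opts$min_signal_frac * S0)
  fit <- wls_dki(matrix(log(s / S0), ncol = 1L), matrix(s^2, ncol = 1L), bvals[dw])
  D <- fit$D[1L]
  K <- if (D > 0) fit$beta[1L] / D^2 else 0
  if (!is.null(opts$k_bounds)) K <- min(max(K, opts$k_bounds[1]), opts$k_bounds[2])
  list(D = D, K = K, valid = isTRUE(fit$ok[1L]) && D > 0 && !clamped)
}

#' Per-direction D and K maps for a whole dataset
#'
#' Applies [fit_dki_direction()] voxelwise for every gradient direction of a
#' dataset (vectorized over voxels). Voxels outside the brain mask are set to
#' 0 and flagged invalid.
#'
#' @param ds a [dwi_dataset()] with at least 3 b-values (incl. b = 0) per
#'   direction.
#' @param opts a [fit_options()].
#' @return A `directional_maps` object: 4D arrays `D` and `K`
#'   (x, y, z, direction), logical 4D `valid`, the `directions` matrix
#'   (n_dir x 3), and `stage` (`"raw"` here).
#' @export
fit_dki_directions <- function(ds, opts = fit_options()) {
  stopifnot(inherits(ds, "dwi_dataset"))
  sp <- split_volumes(ds, by = "direction")
  if (length(sp$baseline) == 0L) stop("dataset has no baseline (b = 0) volume")
  d3 <- dim(ds$signal)[1:3]
  nvox <- prod(d3)
  mask <- ds$brain_mask %||% array(TRUE, d3)
  mv <- as.vector(mask)
  sig <- matrix(ds$signal, nrow = nvox)
  S0 <- rowMeans(sig[, sp$baseline, drop = FALSE])
  ndir <- length(sp$groups)
  Dm <- array(0, c(d3, ndir)); Km <- array(0, c(d3, ndir))
  Vm <- array(FALSE, c(d3, ndir))
  dirs <- matrix(0, ndir, 3)
  use <- mv & S0 > 0
  floor_s <- opts$min_signal_frac * S0[use]
  for (g in seq_len(ndir)) {
    vols <- sp$groups[[g]]
    b <- ds$scheme$bvals[vols]
    if (length(unique(b)) < 2L)
      stop("need at least 2 distinct nonzero b-values per direction (3 incl. baseline)")
    dirs[g, ] <- ds$scheme$bvecs[vols[1L], ]
    s <- t(sig[use, vols, drop = FALSE])            # nb x nvox_used
    clamped <- colSums(s <= 0) > 0L
    s <- pmax(s, rep(floor_s, each = length(vols)))
    y <- log(sweep(s, 2L, S0[use], "/"))
    fit <- wls_dki(y, s^2, b)
    D <- fit$D
    K <- ifelse(D > 0, fit$beta / D^2, 0)
    if (!is.null(opts$k_bounds)) K <- pmin(pmax(K, opts$k_bounds[1]), opts$k_bounds[2])
    dv <- numeric(nvox); kv <- numeric(nvox); vv <- logical(nvox)
    dv[use] <- D; kv[use] <- K
    vv[use] <- fit$ok & D > 0 & !clamped
    Dm[, , , g] <- dv; Km[, , , g] <- kv; Vm[, , , g] <- vv
  }
  structure(list(D = Dm, K = Km, valid = Vm, directions = dirs, stage = "raw"),
            class = "directional_maps")
}

#' Mean diffusivity and mean kurtosis by direction averaging
#'
#' Averages the per-direction D and K maps arithmetically over gradient
#' directions — the computationally light route to MD and MK that places no
#' restriction on the number of directions.
#'
#' @param dm a `directional_maps` object (from [fit_dki_directions()] or
#'   [tensors_to_directional()]).
#' @param only_valid if `TRUE` (default), invalid directions are excluded
#'   per voxel and a voxel with no valid direction gets `MD = MK = 0` and
#'   `valid = FALSE`; if `FALSE`, all directions are averaged as-is (the
#'   plain averaging used when scoring noisy fits, where black-hole voxels
#'   must contribute their error).
#' @param k_range length-2 numeric: directional kurtosis values are clipped
#'   into this interval before averaging, following the interpretable-range
#'   convention of mainstream kurtosis-map software (default `c(-3/7, 10)`).
#'   The unconstrained estimate `K = beta / D^2` is singular as the fitted D
#'   approaches 0 in signal-free voxels, and a single such voxel would
#'   otherwise dominate any map statistic; moderate negative values —
#'   black-hole voxels — remain inside the range and observable. `NULL`
#'   disables clipping.
#' @return A list with 3D maps `MD` (mm^2/s), `MK` (dimensionless) and
#'   logical `valid`.
#' @export
mean_dki_maps <- function(dm, only_valid = TRUE, k_range = c(-3 / 7, 10)) {
  stopifnot(inherits(dm, "directional_maps"))
  d3 <- dim(dm$D)[1:3]
  nvox <- prod(d3)
  Dm <- matrix(dm$D, nrow = nvox)
  Km <- matrix(dm$K, nrow = nvox)
  if (!is.null(k_range)) Km <- pmin(pmax(Km, k_range[1]), k_range[2])
  if (only_valid) {
    Vm <- matrix(dm$valid, nrow = nvox)
    nv <- rowSums(Vm)
    MD <- rowSums(Dm * Vm) / pmax(nv, 1L)
    MK <- rowSums(Km * Vm) / pmax(nv, 1L)
    valid <- nv > 0L
    MD[!valid] <- 0; MK[!valid] <- 0
  } else {
    MD <- rowMeans(Dm)
    MK <- rowMeans(Km)
    valid <- rep(TRUE, nvox)
  }
  list(MD = array(MD, d3), MK = array(MK, d3), valid = array(valid, d3))
}

# -- tensor machinery ---------------------------------------------------------

# Unique-element order for the symmetric diffusion tensor:
# (xx, yy, zz, xy, xz, yz); quadratic-form design row for direction n.
dt_design <- function(dirs) {
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

# Unique-element order for the fully symmetric rank-4 kurtosis tensor
# (15 elements) with permutation multiplicities 1 / 4 / 6 / 12:
# (xxxx, yyyy, zzzz, xxxy, xxxz, xyyy, yyyz, xzzz, yzzz,
#  xxyy, xxzz, yyzz, xxyz, xyyz, xyzz)
kt_design <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z, 4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

pinv_checked <- function(A, min_rank, what) {
  sv <- svd(A)
  rank <- sum(sv$d > 1e-10 * sv$d[1])
  if (rank < min_rank)
    stop(sprintf("rank-deficient design for %s: rank %d < %d (need >= %d non-degenerate directions)",
                 what, rank, min_rank, min_rank))
  sv$v %*% (t(sv$u) / sv$d)
}

#' Reconstruct diffusion and kurtosis tensors from directional maps
#'
#' Fits, per voxel, the symmetric diffusion tensor (6 unique elements) from
#' `D(n) = n' Dt n` and the fully symmetric rank-4 kurtosis tensor (15 unique
#' elements) from `K(n) D(n)^2 = MD^2 W(n)`, where `W(n)` is the quartic form
#' of the kurtosis tensor and `MD = trace(Dt)/3`. Both are linear least
#' squares over directions. At least 6 non-coplanar directions are needed for
#' the diffusion tensor and 15 for the kurtosis tensor; the design-matrix
#' rank is checked (relative singular-value cutoff 1e-10).
#'
#' @param dm a `directional_maps` object.
#' @return A `tensor_field` object: 4D `Dt` (x, y, z, 6), 4D `Wt`
#'   (x, y, z, 15), 3D `MD`, 3D `MK` (direction average of the tensor-implied
#'   K over the fitted directions), and logical 3D `valid` (all directions
#'   valid at that voxel).
#' @export
fit_dki_tensors <- function(dm) {
  stopifnot(inherits(dm, "directional_maps"))
  dirs <- dm$directions
  A <- dt_design(dirs)
  B <- kt_design(dirs)
  Ainv <- pinv_checked(A, 6L, "the diffusion tensor")
  Binv <- pinv_checked(B, 15L, "the kurtosis tensor")
  d3 <- dim(dm$D)[1:3]
  nvox <- prod(d3)
  Dmat <- t(matrix(dm$D, nrow = nvox))          # ndir x nvox
  Kmat <- t(matrix(dm$K, nrow = nvox))
  Dt <- Ainv %*% Dmat                            # 6 x nvox
  MD <- colSums(Dt[1:3, , drop = FALSE]) / 3
  rhs <- Kmat * Dmat^2 / rep(pmax(MD, 1e-12)^2, each = nrow(Dmat))
  Wt <- Binv %*% rhs                             # 15 x nvox
  # tensor-implied directional K, averaged over the fitted directions
  Dn <- A %*% Dt
  Wn <- B %*% Wt
  Kn <- ifelse(Dn > 1e-12, rep(MD, each = nrow(Dn))^2 * Wn / Dn^2, 0)
  MK <- colMeans(Kn)
  zero <- MD <= 0
  Wt[, zero] <- 0
  structure(list(Dt = array(t(Dt), c(d3, 6L)),
                 Wt = array(t(Wt), c(d3, 15L)),
                 MD = array(MD, d3), MK = array(MK, d3),
                 valid = array(apply(dm$valid, 1:3, all), d3)),
            class = "tensor_field")
}

#' Evaluate tensors along arbitrary gradient directions
#'
#' Recomputes per-direction D and K maps from a tensor field at any set of
#' unit directions: `D(n) = n' Dt n` (quadratic form) and
#' `K(n) = MD^2 W(n) / D(n)^2` (quartic form), the route that supports
#' resampling a phantom onto a customized gradient table. Where
#' `D(n) <= tol`, K is set to 0 and the direction flagged invalid.
#'
#' @param tf a `tensor_field` (from [fit_dki_tensors()]).
#' @param directions matrix of unit direction vectors (n x 3).
#' @param tol positive threshold on D(n) below which K is zeroed.
#' @return A `directional_maps` object at stage `"tensor"`.
#' @export
tensors_to_directional <- function(tf, directions, tol = 1e-12) {
  stopifnot(inherits(tf, "tensor_field"))
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L && nrow(directions) == 3L) directions <- t(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("direction vectors must be unit length")
  d3 <- dim(tf$Dt)[1:3]
  nvox <- prod(d3)
  A <- dt_design(directions)
  B <- kt_design(directions)
  Dn <- matrix(tf$Dt, nrow = nvox) %*% t(A)       # nvox x ndir
  Wn <- matrix(tf$Wt, nrow = nvox) %*% t(B)
  MD2 <- as.vector(tf$MD)^2
  ok <- Dn > tol
  Kn <- ifelse(ok, MD2 * Wn / Dn^2, 0)
  ndir <- nrow(directions)
  structure(list(D = array(Dn, c(d3, ndir)), K = array(Kn, c(d3, ndir)),
                 valid = array(ok & as.vector(tf$valid), c(d3, ndir)),
                 directions = directions, stage = "tensor"),
            class = "directional_maps")
}

#' Minimum number of DW measurements for a diffusion tensor
#'
#' Determines, by incremental rank analysis of the quadratic-form design
#' matrix over approximately uniform direction sets, the smallest number of
#' distinct gradient directions whose design reaches full rank (6), and adds
#' the mandatory baseline measurement.
#'
#' @return Integer: minimum total measurements (directions + 1 baseline).
#' @export
min_tensor_measurements <- function() {
  # icosahedral directions: the classical well-conditioned minimal DTI set
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(1, phi, 0), c(-1, phi, 0), c(0, 1, phi),
               c(0, -1, phi), c(phi, 0, 1), c(-phi, 0, 1))
  ico <- ico / sqrt(rowSums(ico^2))
  for (n in seq_len(nrow(ico))) {
    A <- dt_design(ico[seq_len(n), , drop = FALSE])
    if (qr(A)$rank == 6L) return(n + 1L)
  }
  stop("full rank not reached (degenerate direction set)")
}
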