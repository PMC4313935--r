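# Internal helpers shared across modules.

# Reflect a 1-based index into [1, n] (symmetric mirror about the array edge,
# half-sample convention: 0 -> 1, n+1 -> n). Vectorized.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

# Mirror-pad a 3D array by `pad` voxels on every side.
mirror_pad3d <- function(vol, pad) {
  d <- dim(vol)
  ix <- reflect_index(seq.int(1L - pad, d[1] + pad), d[1])
  iy <- reflect_index(seq.int(1L - pad, d[2] + pad), d[2])
  iz <- reflect_index(seq.int(1L - pad, d[3] + pad), d[3])
  vol[ix, iy, iz, drop = FALSE]
}

# Deterministic, approximately uniform unit vectors: spherical Fibonacci lattice.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Binary dilation of a 3D logical mask with a cube of half-width `radius`
# (separable running maximum along each axis).
dilate_mask3d <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (radius <= 0) return(mask)
  m <- mask
  for (axis in 1:3) {
    out <- m
    for (s in seq_len(radius)) {
      n <- dim(m)[axis]
      lo <- pmin(pmax(seq_len(n) - s, 1L), n)
      hi <- pmin(pmax(seq_len(n) + s, 1L), n)
      out <- out |
        switch(axis, m[lo, , , drop = FALSE], m[, lo, , drop = FALSE], m[, , lo, drop = FALSE]) |
        switch(axis, m[hi, , , drop = FALSE], m[, hi, , drop = FALSE], m[, , hi, drop = FALSE])
    }
    m <- out
  }
  m
}

# Derive a child RNG seed from a base seed and stream indices; kept < 2^31.
derive_seed <- function(base_seed, i, j = 0L) {
  as.integer((as.double(base_seed) + 1000003 * as.double(i) + 7919 * as.double(j)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
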