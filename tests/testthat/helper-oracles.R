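# Independent naive reference implementations of the NLM family, coded as
# literal loops over the defining sums. They share only the conventions
# (mirror padding, weights normalized to sum 1, self-weight from the minimum
# search-region distance), not any code, with the package implementation.

oracle_reflect <- function(i, n) {
  p <- 2 * n
  j <- (i - 1) %% p
  ifelse(j < n, j + 1, p - j)
}

oracle_patch_weights <- function(f, rho) {
  g <- exp(-(seq(-f, f))^2 / (2 * rho^2))
  w <- outer(outer(g, g), g)
  w / sum(w)
}

# patch of channel v around center c0 (mirror padded), as a vector
oracle_patch <- function(vol3d, c0, f) {
  d <- dim(vol3d)
  ix <- oracle_reflect(seq(c0[1] - f, c0[1] + f), d[1])
  iy <- oracle_reflect(seq(c0[2] - f, c0[2] + f), d[2])
  iz <- oracle_reflect(seq(c0[3] - f, c0[3] + f), d[3])
  vol3d[ix, iy, iz]
}

oracle_patch_distance <- function(channels, i, j, f, rho) {
  w <- as.numeric(oracle_patch_weights(f, rho))
  ds <- vapply(channels, function(ch)
    sum(w * (as.numeric(oracle_patch(ch, i, f)) -
             as.numeric(oracle_patch(ch, j, f)))^2), numeric(1))
  mean(ds)
}

# naive vector NLM: quadruple loop (voxel x search offsets), no unbiasing
oracle_vnlm <- function(arr, t, f, rho, h) {
  d4 <- dim(arr)
  V <- d4[4]
  channels <- lapply(seq_len(V), function(v) array(arr[, , , v], d4[1:3]))
  out <- arr
  h2 <- h^2
  for (z in seq_len(d4[3])) for (y in seq_len(d4[2])) for (x in seq_len(d4[1])) {
    dists <- numeric(0)
    vals <- NULL
    for (dz in -t:t) for (dy in -t:t) for (dx in -t:t) {
      if (dx == 0 && dy == 0 && dz == 0) next
      dists <- c(dists, oracle_patch_distance(channels, c(x, y, z),
                                              c(x + dx, y + dy, z + dz), f, rho))
      cj <- c(oracle_reflect(x + dx, d4[1]), oracle_reflect(y + dy, d4[2]),
              oracle_reflect(z + dz, d4[3]))
      vals <- rbind(vals, vapply(channels, function(ch) ch[cj[1], cj[2], cj[3]],
                                 numeric(1)))
    }
    w <- exp(-dists / h2)
    wself <- exp(-min(dists) / h2)
    for (v in seq_len(V))
      out[x, y, z, v] <- (sum(w * vals[, v]) +
                          wself * channels[[v]][x, y, z]) / (sum(w) + wself)
  }
  out
}

oracle_nlm3d <- function(vol, t, f, rho, h) {
  arr <- array(vol, c(dim(vol), 1L))
  array(oracle_vnlm(arr, t, f, rho, h), dim(vol))
}

# second-moment variant: weights from magnitude patches, averaging applied to
# squared intensities, output on the magnitude scale
oracle_vnlm_sq <- function(arr, t, f, rho, h) {
  d4 <- dim(arr)
  V <- d4[4]
  channels <- lapply(seq_len(V), function(v) array(arr[, , , v], d4[1:3]))
  out <- arr
  h2 <- h^2
  for (z in seq_len(d4[3])) for (y in seq_len(d4[2])) for (x in seq_len(d4[1])) {
    dists <- numeric(0)
    vals <- NULL
    for (dz in -t:t) for (dy in -t:t) for (dx in -t:t) {
      if (dx == 0 && dy == 0 && dz == 0) next
      dists <- c(dists, oracle_patch_distance(channels, c(x, y, z),
                                              c(x + dx, y + dy, z + dz), f, rho))
      cj <- c(oracle_reflect(x + dx, d4[1]), oracle_reflect(y + dy, d4[2]),
              oracle_reflect(z + dz, d4[3]))
      vals <- rbind(vals, vapply(channels, function(ch) ch[cj[1], cj[2], cj[3]],
                                 numeric(1)))
    }
    w <- exp(-dists / h2)
    wself <- exp(-min(dists) / h2)
    for (v in seq_len(V))
      out[x, y, z, v] <- sqrt((sum(w * vals[, v]^2) +
                               wself * channels[[v]][x, y, z]^2) /
                              (sum(w) + wself))
  }
  out
}
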