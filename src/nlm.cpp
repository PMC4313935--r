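#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric mirror reflection of a 0-based index into [0, n-1]
// (half-sample convention: -1 -> 0, n -> n-1).
static inline int reflect0(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  int j = i % period;
  if (j < 0) j += period;
  return (j < n) ? j : (period - 1 - j);
}

// Vector non-local means over V aligned channels sharing one weight field.
//
// vol:     numeric 4D array flattened column-major, dims (nx, ny, nz, V)
// t:       search radius (voxels)  -> (2t+1)^3 search region
// f:       patch radius (voxels)   -> (2f+1)^3 neighborhood window
// patch_w: Gaussian patch weights over the (2f+1)^3 offsets, sum 1,
//          ordered column-major over (dx, dy, dz) in [-f, f]^3
// h:       smoothing bandwidth (intensity units); weights exp(-d/h^2)
// mask:    logical, voxels to process (others copied through)
// avg_sq:  average squared intensities instead of intensities (weights are
//          still computed from the magnitude patches); the output is the
//          square root of the weighted second moment. This is the averaging
//          domain in which the Rician bias subtraction sqrt(out^2 - 2 s^2)
//          is exact, used by the unbiased (UNLM) variants.
//
// The patch distance d(i, i+s) = sum_k w_k mean_v (P_v(i+k) - P_v(i+s+k))^2
// is, for a fixed search offset s, the separable Gaussian patch kernel
// convolved with the channel-averaged squared-difference field
// U_s(x) = mean_v (pad_v(x) - pad_v(x+s))^2. The filter therefore streams
// over the 124 search offsets, computing each distance field by three 1D
// convolution passes, and accumulates per-voxel weight sums, weighted
// channel sums and the running minimum distance (which sets the center
// voxel's own weight). Boundaries are mirror-padded. Results are exactly
// the per-voxel NLM sums, just evaluated in a cache-friendly order.
// [[Rcpp::export]]
NumericVector vnlm_core_cpp(NumericVector vol, IntegerVector dims,
                            int t, int f, NumericVector patch_w,
                            double h, LogicalVector mask,
                            bool avg_sq = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], V = dims[3];
  const int p = t + f;
  const int npx = nx + 2 * p, npy = ny + 2 * p, npz = nz + 2 * p;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const size_t chanstride = (size_t)npx * npy * npz;

  // mirror-padded copy of each channel
  std::vector<double> pad(chanstride * V);
  std::vector<int> rx(npx), ry(npy), rz(npz);
  for (int i = 0; i < npx; ++i) rx[i] = reflect0(i - p, nx);
  for (int i = 0; i < npy; ++i) ry[i] = reflect0(i - p, ny);
  for (int i = 0; i < npz; ++i) rz[i] = reflect0(i - p, nz);
  for (int v = 0; v < V; ++v) {
    const double* src = &vol[(R_xlen_t)v * nvox];
    double* dst = &pad[(size_t)v * chanstride];
    for (int z = 0; z < npz; ++z)
      for (int y = 0; y < npy; ++y) {
        const double* row = src + ((R_xlen_t)rz[z] * ny + ry[y]) * nx;
        double* orow = dst + ((size_t)z * npy + y) * npx;
        for (int x = 0; x < npx; ++x) orow[x] = row[rx[x]];
      }
  }

  // 1D patch kernel: patch_w is the outer product of one normalized 1D
  // Gaussian with itself, so its 1D factor can be recovered from the
  // central row (w3[k, f, f] = w1[k] * w1[f]^2, and sum(w1) = 1).
  const int fp = 2 * f + 1;
  std::vector<double> w1(fp);
  {
    double tot = 0.0;
    for (int k = 0; k < fp; ++k) {
      // offset (k-f, 0, 0) in column-major (2f+1)^3 ordering
      w1[k] = patch_w[k + fp * f + fp * fp * f];
      tot += w1[k];
    }
    for (int k = 0; k < fp; ++k) w1[k] /= tot;
  }

  // values being averaged: magnitudes, or squares for the unbiased variant
  std::vector<double> avals;
  if (avg_sq) {
    avals.resize(pad.size());
    for (size_t i = 0; i < pad.size(); ++i) avals[i] = pad[i] * pad[i];
  }
  const double* aval = avg_sq ? avals.data() : pad.data();

  const double h2 = h * h;
  NumericVector out(vol.size());

  // per-voxel accumulators over search offsets
  std::vector<double> wsum(nvox, 0.0), dmin(nvox, R_PosInf);
  std::vector<double> num((size_t)nvox * V, 0.0);

  // scratch for the squared-difference field and convolution passes,
  // on the region [p-f, p+n+f) per axis (dims n + 2f)
  const int mx = nx + 2 * f, my = ny + 2 * f, mz = nz + 2 * f;
  std::vector<double> U((size_t)mx * my * mz);
  std::vector<double> C1((size_t)nx * my * mz);
  std::vector<double> C2((size_t)nx * ny * mz);
  std::vector<double> D((size_t)nx * ny * nz);

  const int o0 = p - f;  // padded-space origin of the U region
  for (int sz = -t; sz <= t; ++sz)
    for (int sy = -t; sy <= t; ++sy)
      for (int sx = -t; sx <= t; ++sx) {
        if (!sx && !sy && !sz) continue;
        const std::ptrdiff_t soff = sx + (std::ptrdiff_t)sy * npx +
                                    (std::ptrdiff_t)sz * npx * npy;
        // channel-averaged squared differences
        for (int z = 0; z < mz; ++z)
          for (int y = 0; y < my; ++y) {
            const std::ptrdiff_t base = (std::ptrdiff_t)(z + o0) * npx * npy +
                                        (std::ptrdiff_t)(y + o0) * npx + o0;
            double* urow = &U[((size_t)z * my + y) * mx];
            if (V == 1) {
              const double* a = &pad[base];
              const double* b = &pad[base + soff];
              for (int x = 0; x < mx; ++x) {
                const double dd = a[x] - b[x];
                urow[x] = dd * dd;
              }
            } else {
              for (int x = 0; x < mx; ++x) urow[x] = 0.0;
              for (int v = 0; v < V; ++v) {
                const double* a = &pad[v * chanstride + base];
                const double* b = &pad[v * chanstride + base + soff];
                for (int x = 0; x < mx; ++x) {
                  const double dd = a[x] - b[x];
                  urow[x] += dd * dd;
                }
              }
              const double inv = 1.0 / V;
              for (int x = 0; x < mx; ++x) urow[x] *= inv;
            }
          }
        // separable convolution with the 1D patch kernel: x, then y, then z
        for (size_t i = 0; i < C1.size(); ++i) C1[i] = 0.0;
        for (int z = 0; z < mz; ++z)
          for (int y = 0; y < my; ++y) {
            const double* urow = &U[((size_t)z * my + y) * mx];
            double* crow = &C1[((size_t)z * my + y) * nx];
            for (int k = 0; k < fp; ++k) {
              const double w = w1[k];
              for (int x = 0; x < nx; ++x) crow[x] += w * urow[x + k];
            }
          }
        for (size_t i = 0; i < C2.size(); ++i) C2[i] = 0.0;
        for (int z = 0; z < mz; ++z)
          for (int k = 0; k < fp; ++k) {
            const double w = w1[k];
            const double* src = &C1[((size_t)z * my + k) * nx];
            double* dst = &C2[(size_t)z * ny * nx];
            for (R_xlen_t i = 0; i < (R_xlen_t)ny * nx; ++i)
              dst[i] += w * src[i];
          }
        for (size_t i = 0; i < D.size(); ++i) D[i] = 0.0;
        for (int z = 0; z < nz; ++z)
          for (int k = 0; k < fp; ++k) {
            const double w = w1[k];
            const double* src = &C2[((size_t)z + k) * ny * nx];
            double* dst = &D[(size_t)z * ny * nx];
            for (R_xlen_t i = 0; i < (R_xlen_t)ny * nx; ++i)
              dst[i] += w * src[i];
          }
        // accumulate weights and weighted neighbor values
        for (int z = 0; z < nz; ++z)
          for (int y = 0; y < ny; ++y) {
            const R_xlen_t lin0 = ((R_xlen_t)z * ny + y) * nx;
            const std::ptrdiff_t cb = (std::ptrdiff_t)(z + p) * npx * npy +
                                      (std::ptrdiff_t)(y + p) * npx + p + soff;
            for (int x = 0; x < nx; ++x) {
              const R_xlen_t lin = lin0 + x;
              const double d = D[lin];
              if (d < dmin[lin]) dmin[lin] = d;
              const double w = std::exp(-d / h2);
              wsum[lin] += w;
              for (int v = 0; v < V; ++v)
                num[(size_t)v * nvox + lin] += w * aval[v * chanstride + cb + x];
            }
          }
      }

  const bool lonely = (2 * t + 1) <= 1;  // no other voxel in the search region
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t lin = ((R_xlen_t)z * ny + y) * nx + x;
        if (!mask[lin] || lonely) {
          for (int v = 0; v < V; ++v)
            out[lin + (R_xlen_t)v * nvox] = vol[lin + (R_xlen_t)v * nvox];
          continue;
        }
        const double wself = std::exp(-dmin[lin] / h2);
        const double tot = wsum[lin] + wself;
        const std::ptrdiff_t ci = (std::ptrdiff_t)(z + p) * npx * npy +
                                  (std::ptrdiff_t)(y + p) * npx + (x + p);
        for (int v = 0; v < V; ++v) {
          const double m = (num[(size_t)v * nvox + lin] +
                            wself * aval[v * chanstride + ci]) / tot;
          out[lin + (R_xlen_t)v * nvox] = avg_sq ? std::sqrt(m) : m;
        }
      }
  return out;
}
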