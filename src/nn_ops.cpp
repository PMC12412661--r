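// Minimal 3D convolution kernels for the segmentation network.
// Layout: volumes are R arrays (nx, ny, nz, channels), column-major.
// Weights: (in_ch * k^3) x out_ch matrices with row index
//   r = c*k^3 + dz*k^2 + dy*k + dx  (dx fastest, matching as.vector of an
//   R kernel array [dx, dy, dz]).
// Convolution is correlation with stride 1 and "same" output size; padding
// is zero (pad_mode = 0) or edge-replicate (pad_mode = 1).

#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// gather the im2col block for output voxels [v0, v1), stored transposed
// (one column of `colT` per voxel) so writes are contiguous and the GEMMs
// run without explicit transposition copies
static void im2col_chunk(const double* x, int nx, int ny, int nz, int ic,
                         int k, int dil, int pad_mode,
                         int v0, int v1, arma::mat& colT) {
  const int half = (k - 1) / 2;
  const long vol = (long)nx * ny * nz;
  const int reach = dil * half;
  for (int v = v0; v < v1; ++v) {
    const int i = v % nx, j = (v / nx) % ny, l = v / (nx * ny);
    double* dst = colT.colptr(v - v0);
    const bool interior = i >= reach && i < nx - reach && j >= reach &&
                          j < ny - reach && l >= reach && l < nz - reach;
    for (int c = 0; c < ic; ++c) {
      const double* xc = x + (long)c * vol;
      if (interior) {
        for (int dz = 0; dz < k; ++dz) {
          const long zoff = (long)ny * (l + dil * (dz - half));
          for (int dy = 0; dy < k; ++dy) {
            const double* src =
                xc + (i - reach) + (long)nx * (j + dil * (dy - half) + zoff);
            if (dil == 1) {
              for (int dx = 0; dx < k; ++dx) *dst++ = src[dx];
            } else {
              for (int dx = 0; dx < k; ++dx) *dst++ = src[dx * dil];
            }
          }
        }
        continue;
      }
      for (int dz = 0; dz < k; ++dz) {
        int zz = l + dil * (dz - half);
        for (int dy = 0; dy < k; ++dy) {
          int yy = j + dil * (dy - half);
          for (int dx = 0; dx < k; ++dx) {
            int xx = i + dil * (dx - half);
            double val;
            if (pad_mode == 1) {
              val = xc[clampi(xx, 0, nx - 1) +
                       (long)nx * (clampi(yy, 0, ny - 1) +
                                   (long)ny * clampi(zz, 0, nz - 1))];
            } else {
              val = (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                     zz < 0 || zz >= nz)
                        ? 0.0
                        : xc[xx + (long)nx * (yy + (long)ny * zz)];
            }
            *dst++ = val;
          }
        }
      }
    }
  }
}

static int chunk_rows(int ic, int k) {
  long cols = (long)ic * k * k * k;
  long target = 1L << 22;  // ~4M doubles (32 MB) per im2col chunk
  long rows = target / cols;
  if (rows < 512) rows = 512;
  return (int)rows;
}

// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericMatrix W,
                                 NumericVector bias, int k, int dil,
                                 int pad_mode) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ic = d.size() > 3 ? d[3] : 1;
  const int oc = W.ncol();
  const long vol = (long)nx * ny * nz;
  arma::mat Wm(W.begin(), W.nrow(), oc, false);
  NumericVector out(vol * oc);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, oc);
  arma::mat outm(out.begin(), vol, oc, false);
  const int chunk = chunk_rows(ic, k);
  arma::mat colT((long)ic * k * k * k, chunk);
  for (long v0 = 0; v0 < vol; v0 += chunk) {
    int v1 = (int)std::min(vol, v0 + chunk);
    int n = v1 - (int)v0;
    im2col_chunk(x.begin(), nx, ny, nz, ic, k, dil, pad_mode, (int)v0, v1,
                 colT);
    outm.rows(v0, v1 - 1) = colT.cols(0, n - 1).t() * Wm;
  }
  for (int c = 0; c < oc; ++c) outm.col(c) += bias[c];
  return out;
}

// [[Rcpp::export]]
NumericMatrix conv3d_grad_weights_cpp(NumericVector x, NumericVector dout,
                                      int k, int dil, int pad_mode, int oc) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int ic = d.size() > 3 ? d[3] : 1;
  const long vol = (long)nx * ny * nz;
  arma::mat doutm(dout.begin(), vol, oc, false);
  arma::mat acc((long)ic * k * k * k, oc, arma::fill::zeros);
  const int chunk = chunk_rows(ic, k);
  arma::mat colT((long)ic * k * k * k, chunk);
  for (long v0 = 0; v0 < vol; v0 += chunk) {
    int v1 = (int)std::min(vol, v0 + chunk);
    int n = v1 - (int)v0;
    im2col_chunk(x.begin(), nx, ny, nz, ic, k, dil, pad_mode, (int)v0, v1,
                 colT);
    acc += colT.cols(0, n - 1) * doutm.rows(v0, v1 - 1);
  }
  return wrap(acc);
}

// [[Rcpp::export]]
NumericVector conv3d_grad_input_cpp(NumericVector dout, NumericMatrix W,
                                    IntegerVector xdim, int k, int dil,
                                    int pad_mode) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int ic = xdim.size() > 3 ? xdim[3] : 1;
  const int oc = W.ncol();
  const long vol = (long)nx * ny * nz;
  const int half = (k - 1) / 2;
  arma::mat Wm(W.begin(), W.nrow(), oc, false);
  arma::mat doutm(dout.begin(), vol, oc, false);
  NumericVector dx(vol * ic);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, ic);
  double* dxp = dx.begin();
  const int chunk = chunk_rows(ic, k);
  for (long v0 = 0; v0 < vol; v0 += chunk) {
    long v1 = std::min(vol, v0 + chunk);
    // transposed col2im scatter: one contiguous column per voxel
    arma::mat colgradT = Wm * doutm.rows(v0, v1 - 1).t();  // (ic*k^3) x n
    for (long v = v0; v < v1; ++v) {
      const int i = v % nx, j = (v / nx) % ny, l = (int)(v / ((long)nx * ny));
      const double* src = colgradT.colptr(v - v0);
      for (int c = 0; c < ic; ++c) {
        double* dc = dxp + (long)c * vol;
        for (int dz = 0; dz < k; ++dz) {
          int zz = l + dil * (dz - half);
          for (int dy = 0; dy < k; ++dy) {
            int yy = j + dil * (dy - half);
            for (int dxo = 0; dxo < k; ++dxo, ++src) {
              int xx = i + dil * (dxo - half);
              if (pad_mode == 1) {
                dc[clampi(xx, 0, nx - 1) +
                   (long)nx * (clampi(yy, 0, ny - 1) +
                               (long)ny * clampi(zz, 0, nz - 1))] += *src;
              } else {
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                    zz >= nz)
                  continue;
                dc[xx + (long)nx * (yy + (long)ny * zz)] += *src;
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// 2x2x2 max pooling (dims must be even); returns pooled values and the
// 1-based linear argmax index into the input, for the backward pass.
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int nc = d.size() > 3 ? d[3] : 1;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const long ovol = (long)ox * oy * oz;
  NumericVector out(ovol * nc);
  IntegerVector arg(ovol * nc);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  const double* xp = x.begin();
  const long vol = (long)nx * ny * nz;
  long o = 0;
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + (long)c * vol;
    for (int l = 0; l < oz; ++l)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++o) {
          double best = -1e300;
          long bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long idx = (2 * i + dx) +
                           (long)nx * ((2 * j + dy) + (long)ny * (2 * l + dz));
                if (xc[idx] > best) {
                  best = xc[idx];
                  bidx = idx + (long)c * vol;
                }
              }
          out[o] = best;
          arg[o] = (int)(bidx + 1);
        }
  }
  return List::create(_["values"] = out, _["argmax"] = arg);
}

// Direct single-channel convolution (and its weight gradient) for the LoG
// stream: avoids the im2col gather, which dominates for large kernels.
// Edge-replicate padding, stride 1, "same" output.
// [[Rcpp::export]]
NumericVector conv3d_single_cpp(NumericVector x, NumericVector w, int k) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int half = (k - 1) / 2;
  const long vol = (long)nx * ny * nz;
  NumericVector out(vol);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 1);
  const double* xp = x.begin();
  double* op = out.begin();
  // precompute clamped index tables per axis
  std::vector<int> cx((size_t)nx * k), cy((size_t)ny * k), cz((size_t)nz * k);
  for (int i = 0; i < nx; ++i)
    for (int t = 0; t < k; ++t)
      cx[(size_t)i * k + t] = clampi(i + t - half, 0, nx - 1);
  for (int j = 0; j < ny; ++j)
    for (int t = 0; t < k; ++t)
      cy[(size_t)j * k + t] = clampi(j + t - half, 0, ny - 1);
  for (int l = 0; l < nz; ++l)
    for (int t = 0; t < k; ++t)
      cz[(size_t)l * k + t] = clampi(l + t - half, 0, nz - 1);
  const double* wp = w.begin();
  for (int l = 0; l < nz; ++l)
    for (int j = 0; j < ny; ++j) {
      const int* cyj = &cy[(size_t)j * k];
      const int* czl = &cz[(size_t)l * k];
      for (int i = 0; i < nx; ++i) {
        const int* cxi = &cx[(size_t)i * k];
        double s = 0;
        int r = 0;
        for (int dz = 0; dz < k; ++dz) {
          const long zoff = (long)ny * czl[dz];
          for (int dy = 0; dy < k; ++dy) {
            const long yoff = (long)nx * (cyj[dy] + zoff);
            for (int dx = 0; dx < k; ++dx, ++r)
              s += wp[r] * xp[cxi[dx] + yoff];
          }
        }
        op[i + (long)nx * (j + (long)ny * l)] = s;
      }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector conv3d_single_gradw_cpp(NumericVector x, NumericVector dout,
                                      int k) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int half = (k - 1) / 2;
  NumericVector dw((long)k * k * k);
  const double* xp = x.begin();
  const double* dp = dout.begin();
  std::vector<int> cx((size_t)nx * k), cy((size_t)ny * k), cz((size_t)nz * k);
  for (int i = 0; i < nx; ++i)
    for (int t = 0; t < k; ++t)
      cx[(size_t)i * k + t] = clampi(i + t - half, 0, nx - 1);
  for (int j = 0; j < ny; ++j)
    for (int t = 0; t < k; ++t)
      cy[(size_t)j * k + t] = clampi(j + t - half, 0, ny - 1);
  for (int l = 0; l < nz; ++l)
    for (int t = 0; t < k; ++t)
      cz[(size_t)l * k + t] = clampi(l + t - half, 0, nz - 1);
  double* dwp = dw.begin();
  for (int l = 0; l < nz; ++l)
    for (int j = 0; j < ny; ++j) {
      const int* cyj = &cy[(size_t)j * k];
      const int* czl = &cz[(size_t)l * k];
      for (int i = 0; i < nx; ++i) {
        const int* cxi = &cx[(size_t)i * k];
        const double g = dp[i + (long)nx * (j + (long)ny * l)];
        if (g == 0) continue;
        int r = 0;
        for (int dz = 0; dz < k; ++dz) {
          const long zoff = (long)ny * czl[dz];
          for (int dy = 0; dy < k; ++dy) {
            const long yoff = (long)nx * (cyj[dy] + zoff);
            for (int dx = 0; dx < k; ++dx, ++r)
              dwp[r] += g * xp[cxi[dx] + yoff];
          }
        }
      }
    }
  return dw;
}
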