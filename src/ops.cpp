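// Low-level tensor kernels for the 3D segmentation network.
//
// Array layout convention (column-major, matching R): feature tensors are
// (D, H, W, C, N) with depth fastest.  Convolution weights arrive as a
// (k^3 * Cin) x Cout matrix whose row index is kd + k*(kh + k*(kw + k*ci)).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long long vox(long long d, long long h, long long w,
                            long long D, long long H) {
  return d + D * (h + H * w);
}

// Direct tap-loop convolution: for every kernel tap the valid output range
// is a contiguous block per (h, w) column, so the inner depth loop is a
// branch-free AXPY / dot over contiguous memory.

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector b,
                            int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int K = k * k * k * Cin, Cout = Wm.ncol();
  if (Wm.nrow() != K) stop("conv3d: weight shape mismatch");
  const long long DH = (long long)D * H, DHW = DH * W;
  NumericVector y((long long)DHW * Cout * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long long)n * DHW * Cin;
    double* yn = y.begin() + (long long)n * DHW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (long long)co * DHW;
      const double bb = b[co];
      for (long long i = 0; i < DHW; ++i) yc[i] = bb;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (long long)ci * DHW;
        for (int kw = 0; kw < k; ++kw) {
          const int wlo = std::max(0, pad - kw), whi = std::min(W, W + pad - kw);
          for (int kh = 0; kh < k; ++kh) {
            const int hlo = std::max(0, pad - kh), hhi = std::min(H, H + pad - kh);
            for (int kd = 0; kd < k; ++kd) {
              const double wv = Wm(kd + k * (kh + k * kw) + k * k * k * ci, co);
              if (wv == 0.0) continue;
              const int dlo = std::max(0, pad - kd), dhi = std::min(D, D + pad - kd);
              const int len = dhi - dlo;
              const long long shift = (long long)(kd - pad) +
                D * (long long)(kh - pad) + DH * (long long)(kw - pad);
              for (int w = wlo; w < whi; ++w)
                for (int h = hlo; h < hhi; ++h) {
                  double* yp = yc + vox(dlo, h, w, D, H);
                  const double* xp = xc + vox(dlo, h, w, D, H) + shift;
                  for (int d = 0; d < len; ++d) yp[d] += wv * xp[d];
                }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(D, H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector dims,
                   NumericMatrix Wm, NumericVector dy,
                   int k, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int K = k * k * k * Cin, Cout = Wm.ncol();
  const long long DH = (long long)D * H, DHW = DH * W;
  NumericVector dx((long long)DHW * Cin * N);
  NumericMatrix dW(K, Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (long long)n * DHW * Cin;
    const double* dyn = dy.begin() + (long long)n * DHW * Cout;
    double* dxn = dx.begin() + (long long)n * DHW * Cin;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (long long)co * DHW;
      double acc = 0.0;
      for (long long i = 0; i < DHW; ++i) acc += dyc[i];
      db[co] += acc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = xn + (long long)ci * DHW;
        double* dxc = dxn + (long long)ci * DHW;
        for (int kw = 0; kw < k; ++kw) {
          const int wlo = std::max(0, pad - kw), whi = std::min(W, W + pad - kw);
          for (int kh = 0; kh < k; ++kh) {
            const int hlo = std::max(0, pad - kh), hhi = std::min(H, H + pad - kh);
            for (int kd = 0; kd < k; ++kd) {
              const int row = kd + k * (kh + k * kw) + k * k * k * ci;
              const double wv = Wm(row, co);
              const int dlo = std::max(0, pad - kd), dhi = std::min(D, D + pad - kd);
              const int len = dhi - dlo;
              const long long shift = (long long)(kd - pad) +
                D * (long long)(kh - pad) + DH * (long long)(kw - pad);
              double wacc = 0.0;
              for (int w = wlo; w < whi; ++w)
                for (int h = hlo; h < hhi; ++h) {
                  const long long o = vox(dlo, h, w, D, H);
                  const double* dyp = dyc + o;
                  const double* xp = xc + o + shift;
                  double* dxp = dxc + o + shift;
                  for (int d = 0; d < len; ++d) {
                    wacc += xp[d] * dyp[d];
                    dxp[d] += wv * dyp[d];
                  }
                }
              dW(row, co) += wacc;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, Cin, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Transposed convolution, kernel 2, stride 2 (resolution doubling).
// Weight matrix: Cin x (8 * Cout), column index = (kd + 2*kh + 4*kw) + 8*co.

// [[Rcpp::export]]
NumericVector cpp_convt3d_fw(NumericVector x, IntegerVector dims,
                             NumericMatrix Wm, NumericVector b) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int Cout = Wm.ncol() / 8;
  const long long DHW = (long long)D * H * W;
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  const long long oDHW = (long long)oD * oH * oW;
  NumericVector y(oDHW * Cout * N);
  arma::mat Wa(Wm.begin(), Cin, 8 * Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (long long)n * DHW * Cin,
                DHW, Cin, false);
    arma::mat Y = X * Wa;  // DHW x 8Cout
    double* yn = y.begin() + (long long)n * oDHW * Cout;
    for (int co = 0; co < Cout; ++co) {
      double* yc = yn + (long long)co * oDHW;
      const double bb = b[co];
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          for (int kd = 0; kd < 2; ++kd) {
            const double* src = Y.colptr((kd + 2 * kh + 4 * kw) + 8 * co);
            for (int w = 0; w < W; ++w)
              for (int h = 0; h < H; ++h) {
                const double* s = src + vox(0, h, w, D, H);
                double* dcol = yc + vox((long long)kd, 2 * h + kh, 2 * w + kw,
                                        oD, oH);
                for (int d = 0; d < D; ++d) dcol[2 * d] = s[d] + bb;
              }
          }
    }
  }
  y.attr("dim") = IntegerVector::create(oD, oH, oW, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convt3d_bw(NumericVector x, IntegerVector dims,
                    NumericMatrix Wm, NumericVector dy) {
  const int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], N = dims[4];
  const int Cout = Wm.ncol() / 8;
  const long long DHW = (long long)D * H * W;
  const int oD = 2 * D, oH = 2 * H;
  const long long oDHW = DHW * 8;
  arma::mat Wa(Wm.begin(), Cin, 8 * Cout, false);
  NumericVector dx((long long)DHW * Cin * N);
  arma::mat dW(Cin, 8 * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat dYg(DHW, 8 * Cout);  // gathered
    const double* dyn = dy.begin() + (long long)n * oDHW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyn + (long long)co * oDHW;
      double acc = 0.0;
      for (long long i = 0; i < oDHW; ++i) acc += dyc[i];
      db[co] += acc;
      for (int kw = 0; kw < 2; ++kw)
        for (int kh = 0; kh < 2; ++kh)
          for (int kd = 0; kd < 2; ++kd) {
            double* dst = dYg.colptr((kd + 2 * kh + 4 * kw) + 8 * co);
            for (int w = 0; w < W; ++w)
              for (int h = 0; h < H; ++h) {
                const double* scol = dyc + vox((long long)kd, 2 * h + kh,
                                               2 * w + kw, oD, oH);
                double* d0 = dst + vox(0, h, w, D, H);
                for (int d = 0; d < D; ++d) d0[d] = scol[2 * d];
              }
          }
    }
    arma::mat X(const_cast<double*>(x.begin()) + (long long)n * DHW * Cin,
                DHW, Cin, false);
    dW += X.t() * dYg;
    arma::mat dX = dYg * Wa.t();
    std::copy(dX.begin(), dX.end(), dx.begin() + (long long)n * DHW * Cin);
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, Cin, N);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// Max pooling, kernel 2, stride 2; returns pooled values and argmax offsets.

// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3], N = dims[4];
  if (D % 2 || H % 2 || W % 2) stop("maxpool: odd spatial dimension");
  const int oD = D / 2, oH = H / 2, oW = W / 2;
  const long long DHW = (long long)D * H * W;
  const long long oDHW = (long long)oD * oH * oW;
  NumericVector y(oDHW * C * N);
  NumericVector idx(oDHW * C * N);  // 1-based global offsets into x
  long long o = 0;
  for (long long cn = 0; cn < (long long)C * N; ++cn) {
    const double* xc = x.begin() + cn * DHW;
    for (int w = 0; w < oW; ++w)
      for (int h = 0; h < oH; ++h)
        for (int d = 0; d < oD; ++d, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          long long bi = -1;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                const long long ii = vox(2 * d + kd, 2 * h + kh, 2 * w + kw,
                                         D, H);
                if (xc[ii] > best) { best = xc[ii]; bi = ii; }
              }
          y[o] = best;
          idx[o] = (double)(cn * DHW + bi + 1);
        }
  }
  y.attr("dim") = IntegerVector::create(oD, oH, oW, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bw(NumericVector dy, NumericVector idx,
                               double xlen) {
  NumericVector dx((long long)xlen);
  for (long long i = 0; i < dy.size(); ++i)
    dx[(long long)idx[i] - 1] += dy[i];
  return dx;
}

// Single-channel 3D resize (trilinear or nearest); half-voxel centre mapping.

// [[Rcpp::export]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector dims,
                           IntegerVector odims, bool nearest) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int oD = odims[0], oH = odims[1], oW = odims[2];
  NumericVector y((long long)oD * oH * oW);
  const double sd = (double)D / oD, sh = (double)H / oH, sw = (double)W / oW;
  long long o = 0;
  for (int w = 0; w < oW; ++w) {
    double fw = (w + 0.5) * sw - 0.5;
    for (int h = 0; h < oH; ++h) {
      double fh = (h + 0.5) * sh - 0.5;
      for (int d = 0; d < oD; ++d, ++o) {
        double fd = (d + 0.5) * sd - 0.5;
        if (nearest) {
          int id = std::min(D - 1, std::max(0, (int)std::lround(fd)));
          int ih = std::min(H - 1, std::max(0, (int)std::lround(fh)));
          int iw = std::min(W - 1, std::max(0, (int)std::lround(fw)));
          y[o] = x[vox(id, ih, iw, D, H)];
        } else {
          int d0 = (int)std::floor(fd), h0 = (int)std::floor(fh),
              w0 = (int)std::floor(fw);
          double td = fd - d0, th = fh - h0, tw = fw - w0;
          double acc = 0.0;
          for (int b = 0; b < 8; ++b) {
            int dd = d0 + (b & 1), hh = h0 + ((b >> 1) & 1),
                ww = w0 + ((b >> 2) & 1);
            double wgt = ((b & 1) ? td : 1 - td) * (((b >> 1) & 1) ? th : 1 - th) *
                         (((b >> 2) & 1) ? tw : 1 - tw);
            dd = std::min(D - 1, std::max(0, dd));
            hh = std::min(H - 1, std::max(0, hh));
            ww = std::min(W - 1, std::max(0, ww));
            acc += wgt * x[vox(dd, hh, ww, D, H)];
          }
          y[o] = acc;
        }
      }
    }
  }
  y.attr("dim") = odims;
  return y;
}

// Connected components of a binary mask, 26-connectivity.

// [[Rcpp::export]]
IntegerVector cpp_cc_label(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long long n = (long long)D * H * W;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int d = (int)(v % D), h = (int)((v / D) % H), w = (int)(v / ((long long)D * H));
      for (int dw = -1; dw <= 1; ++dw)
        for (int dh = -1; dh <= 1; ++dh)
          for (int dd = -1; dd <= 1; ++dd) {
            if (!dd && !dh && !dw) continue;
            int nd = d + dd, nh = h + dh, nw = w + dw;
            if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
              continue;
            long long u = vox(nd, nh, nw, D, H);
            if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Surface voxels: foreground with a face-adjacent (6-connectivity) background
// neighbour; the outside of the grid counts as background.

// [[Rcpp::export]]
LogicalVector cpp_boundary(IntegerVector mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  LogicalVector out((long long)D * H * W);
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  long long v = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d, ++v) {
        if (!mask[v]) continue;
        bool bd = false;
        for (int i = 0; i < 6 && !bd; ++i) {
          int nd = d + off[i][0], nh = h + off[i][1], nw = w + off[i][2];
          if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W)
            bd = true;
          else if (!mask[vox(nd, nh, nw, D, H)])
            bd = true;
        }
        out[v] = bd;
      }
  out.attr("dim") = dims;
  return out;
}

// For each row of A (physical coordinates), the minimum Euclidean distance
// to any row of B.

// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      const double dd = d0 * d0 + d1 * d1 + d2 * d2;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Column-wise max and argmax (1-based) of a matrix.

// [[Rcpp::export]]
List cpp_colmax(NumericMatrix X) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericVector mx(nc);
  IntegerVector am(nc);
  for (int j = 0; j < nc; ++j) {
    const double* col = &X(0, j);
    double best = col[0]; int bi = 0;
    for (int i = 1; i < nr; ++i)
      if (col[i] > best) { best = col[i]; bi = i; }
    mx[j] = best; am[j] = bi + 1;
  }
  return List::create(_["max"] = mx, _["which"] = am);
}
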