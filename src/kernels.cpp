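// Low-level numeric kernels: 3D convolution (im2col + BLAS), max-pooling with
// argmax indices, index-preserving unpooling, an exact Euclidean distance
// transform and 6-connectivity component labelling.
//
// Tensors are R arrays of dim (C, X, Y, Z), column-major, so a tensor is also
// a (C x N) matrix with N = X*Y*Z spatial positions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t spatial_n(const IntegerVector& sh) {
  return (R_xlen_t)sh[0] * sh[1] * sh[2];
}

// 3x3x3 pad-1 convolution via "shift-GEMM": the input is copied once into
// a zero-padded buffer (C x (X+2)(Y+2)(Z+2)); each of the 27 kernel offsets
// then contributes one dense GEMM over a contiguous shifted view. No im2col
// matrix is ever materialized, which keeps the working set small.

static void pad_input(const double* x, int C, int X, int Y, int Z,
                      arma::mat& xp) {
  int Xp = X + 2, Yp = Y + 2;
  xp.zeros();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const double* src = x + ((R_xlen_t)X * (y + (R_xlen_t)Y * z)) * C;
      double* dst = xp.colptr((R_xlen_t)1 + Xp * ((y + 1) + (R_xlen_t)Yp * (z + 1)));
      std::copy(src, src + (R_xlen_t)C * X, dst);
    }
}

// [[Rcpp::export]]
NumericVector conv3_fw(NumericVector x, IntegerVector shape, NumericMatrix w,
                       NumericVector b) {
  // x: (Cin, X, Y, Z); w: (Cout, 27*Cin) with column o*Cin+ci for offset
  // o = (dx+1) + 3*(dy+1) + 9*(dz+1); returns (Cout, X, Y, Z)
  int Cout = w.nrow();
  int Cin = w.ncol() / 27;
  int X = shape[0], Y = shape[1], Z = shape[2];
  int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  R_xlen_t Np = (R_xlen_t)Xp * Yp * Zp;
  arma::mat xp(Cin, Np);
  pad_input(x.begin(), Cin, X, Y, Z, xp);
  arma::mat W(w.begin(), Cout, w.ncol(), false);
  arma::mat yp(Cout, Np, arma::fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        R_xlen_t delta = dx + (R_xlen_t)Xp * (dy + (R_xlen_t)Yp * dz);
        R_xlen_t lo = std::max((R_xlen_t)0, -delta);
        R_xlen_t hi = std::min(Np, Np - delta);
        if (hi <= lo) continue;
        yp.cols(lo, hi - 1) +=
          W.cols(o * Cin, (o + 1) * Cin - 1) * xp.cols(lo + delta, hi - 1 + delta);
      }
  NumericVector yv((R_xlen_t)Cout * X * Y * Z);
  double* py = yv.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const double* src = yp.colptr((R_xlen_t)1 + Xp * ((y + 1) + (R_xlen_t)Yp * (z + 1)));
      double* dst = py + ((R_xlen_t)X * (y + (R_xlen_t)Y * z)) * Cout;
      std::copy(src, src + (R_xlen_t)Cout * X, dst);
    }
  arma::mat Yv(py, Cout, (R_xlen_t)X * Y * Z, false);
  Yv.each_col() += arma::vec(b.begin(), Cout, false);
  yv.attr("dim") = IntegerVector::create(Cout, X, Y, Z);
  return yv;
}

// [[Rcpp::export]]
List conv3_bw(NumericVector x, IntegerVector shape, NumericMatrix w,
              NumericVector dy) {
  int Cout = w.nrow();
  int Cin = w.ncol() / 27;
  int X = shape[0], Y = shape[1], Z = shape[2];
  int Xp = X + 2, Yp = Y + 2, Zp = Z + 2;
  R_xlen_t Np = (R_xlen_t)Xp * Yp * Zp;
  arma::mat xp(Cin, Np), dyp(Cout, Np);
  pad_input(x.begin(), Cin, X, Y, Z, xp);
  pad_input(dy.begin(), Cout, X, Y, Z, dyp);
  arma::mat W(w.begin(), Cout, w.ncol(), false);
  NumericMatrix dwv(Cout, 27 * Cin);
  arma::mat dW(dwv.begin(), Cout, 27 * Cin, false);
  arma::mat dxp(Cin, Np, arma::fill::zeros);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        R_xlen_t delta = dx + (R_xlen_t)Xp * (dy_ + (R_xlen_t)Yp * dz);
        R_xlen_t lo = std::max((R_xlen_t)0, -delta);
        R_xlen_t hi = std::min(Np, Np - delta);
        if (hi <= lo) continue;
        // dW_o = dY * shifted(X)^T ; dX(shifted) += W_o^T * dY
        dW.cols(o * Cin, (o + 1) * Cin - 1) +=
          dyp.cols(lo, hi - 1) * xp.cols(lo + delta, hi - 1 + delta).t();
        dxp.cols(lo + delta, hi - 1 + delta) +=
          W.cols(o * Cin, (o + 1) * Cin - 1).t() * dyp.cols(lo, hi - 1);
      }
  NumericVector dxv((R_xlen_t)Cin * X * Y * Z);
  double* pdx = dxv.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      const double* src = dxp.colptr((R_xlen_t)1 + Xp * ((y + 1) + (R_xlen_t)Yp * (z + 1)));
      double* dst = pdx + ((R_xlen_t)X * (y + (R_xlen_t)Y * z)) * Cin;
      std::copy(src, src + (R_xlen_t)Cin * X, dst);
    }
  NumericVector dbv(Cout);
  arma::vec db(dbv.begin(), Cout, false);
  arma::mat dY(dy.begin(), Cout, (R_xlen_t)X * Y * Z, false);
  db = arma::sum(dY, 1);
  dxv.attr("dim") = IntegerVector::create(Cin, X, Y, Z);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List maxpool_fw(NumericVector x, IntegerVector shape, IntegerVector factor) {
  // x: (C, X, Y, Z); factor: 3 ints in {1,2}; dims must be divisible.
  IntegerVector xd = x.attr("dim");
  int C = xd[0];
  int X = shape[0], Y = shape[1], Z = shape[2];
  int fx = factor[0], fy = factor[1], fz = factor[2];
  int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  R_xlen_t No = (R_xlen_t)Xo * Yo * Zo;
  NumericVector yv((R_xlen_t)C * No);
  IntegerVector idx((R_xlen_t)C * No); // 1-based linear index into x
  const double* px = x.begin();
  double* py = yv.begin();
  int* pi = idx.begin();
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox) {
        R_xlen_t obase = ((R_xlen_t)ox + (R_xlen_t)Xo * (oy + (R_xlen_t)Yo * oz)) * C;
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bi = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                R_xlen_t src = ((R_xlen_t)(ox * fx + dx) +
                                (R_xlen_t)X * ((oy * fy + dy) +
                                (R_xlen_t)Y * (oz * fz + dz))) * C + c;
                if (px[src] > best) { best = px[src]; bi = src; }
              }
          py[obase + c] = best;
          pi[obase + c] = (int)(bi + 1);
        }
      }
  yv.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["y"] = yv, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector unpool_fw(NumericVector y, IntegerVector idx, IntegerVector out_dim) {
  // scatter y into zeros of dim out_dim at recorded indices
  R_xlen_t n = (R_xlen_t)out_dim[0] * out_dim[1] * out_dim[2] * out_dim[3];
  NumericVector xv(n);
  const double* py = y.begin();
  const int* pi = idx.begin();
  double* px = xv.begin();
  R_xlen_t m = y.size();
  for (R_xlen_t i = 0; i < m; ++i) px[pi[i] - 1] += py[i];
  xv.attr("dim") = out_dim;
  return xv;
}

// [[Rcpp::export]]
NumericVector gather_idx(NumericVector dx, IntegerVector idx, IntegerVector out_dim) {
  // backward of unpool: gather gradient at recorded indices
  R_xlen_t m = idx.size();
  NumericVector dyv(m);
  const double* p = dx.begin();
  const int* pi = idx.begin();
  for (R_xlen_t i = 0; i < m; ++i) dyv[i] = p[pi[i] - 1];
  dyv.attr("dim") = out_dim;
  return dyv;
}

// ---- Euclidean distance transform (Felzenszwalb & Huttenlocher) -----------

static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  // squared distance along one axis, sample spacing sqrt(s2)
  int k = 0;
  v[0] = 0;
  zbuf[0] = -std::numeric_limits<double>::infinity();
  zbuf[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    while (true) {
      int p = v[k];
      double denom = 2.0 * s2 * (q - p);
      double sint = ((fq + s2 * (double)q * q) - (f[p] + s2 * (double)p * p)) / denom;
      if (sint <= zbuf[k]) { --k; continue; }
      ++k; v[k] = q; zbuf[k] = sint; zbuf[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    int p = v[k];
    double dq = (double)(q - p);
    d[q] = s2 * dq * dq + f[p];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector shape, NumericVector spacing) {
  // squared mm distance from each voxel to the nearest TRUE voxel
  int X = shape[0], Y = shape[1], Z = shape[2];
  R_xlen_t N = (R_xlen_t)X * Y * Z;
  NumericVector dv(N);
  double* d = dv.begin();
  const double BIG = 1e20; // finite stand-in for "no site": keeps parabola
                           // intersections well-defined
  for (R_xlen_t i = 0; i < N; ++i) d[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), tmp(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zbuf(nmax + 1);
  // x axis
  double s2 = spacing[0] * spacing[0];
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y) {
      double* row = d + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
      dt1d(row, tmp.data(), X, s2, v, zbuf);
      std::copy(tmp.data(), tmp.data() + X, row);
    }
  // y axis
  s2 = spacing[1] * spacing[1];
  for (int z = 0; z < Z; ++z)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = d[(R_xlen_t)x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)];
      dt1d(f.data(), tmp.data(), Y, s2, v, zbuf);
      for (int y = 0; y < Y; ++y) d[(R_xlen_t)x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)] = tmp[y];
    }
  // z axis
  s2 = spacing[2] * spacing[2];
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int z = 0; z < Z; ++z) f[z] = d[(R_xlen_t)x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)];
      dt1d(f.data(), tmp.data(), Z, s2, v, zbuf);
      for (int z = 0; z < Z; ++z) d[(R_xlen_t)x + X * ((R_xlen_t)y + (R_xlen_t)Y * z)] = tmp[z];
    }
  dv.attr("dim") = shape;
  return dv;
}

// [[Rcpp::export]]
IntegerVector label_components(LogicalVector mask, IntegerVector shape) {
  // 6-connectivity labelling; labels 1..k, 0 outside mask
  int X = shape[0], Y = shape[1], Z = shape[2];
  R_xlen_t N = (R_xlen_t)X * Y * Z;
  IntegerVector lab(N);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur / ((R_xlen_t)X * Y));
      int rem = (int)(cur - (R_xlen_t)z * X * Y);
      int y = rem / X, x = rem - y * X;
      for (int k = 0; k < 6; ++k) {
        int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        R_xlen_t ni = (R_xlen_t)nx + X * ((R_xlen_t)ny + (R_xlen_t)Y * nz);
        if (mask[ni] && !lab[ni]) { lab[ni] = next; stack.push_back(ni); }
      }
    }
  }
  lab.attr("dim") = shape;
  return lab;
}
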