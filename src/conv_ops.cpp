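#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// All volumes are stored as column-major arrays with dims (n1, n2, n3, C);
// kernels as (k1, k2, k3, Cin, Cout) with odd spatial extents and "same"
// zero padding. 2D inputs are represented upstream with n3 = 1 and k3 = 1.

static inline int idx4(int i1, int i2, int i3, int c, int n1, int n2, int n3) {
  return i1 + n1 * (i2 + n2 * (i3 + n3 * c));
}

// Shifted-accumulate core: dst[i, cd] += wv * src[i + d, cs] over the valid
// range of i, with a contiguous (vectorizable) inner loop along axis 1.
static void accum_shift(double* dst, const double* src, double wv,
                        int d1, int d2, int d3, int n1, int n2, int n3) {
  if (wv == 0.0) return;
  const int i1lo = std::max(0, -d1), i1hi = std::min(n1, n1 - d1);
  const int i2lo = std::max(0, -d2), i2hi = std::min(n2, n2 - d2);
  const int i3lo = std::max(0, -d3), i3hi = std::min(n3, n3 - d3);
  const int len = i1hi - i1lo;
  if (len <= 0) return;
  for (int i3 = i3lo; i3 < i3hi; ++i3) {
    for (int i2 = i2lo; i2 < i2hi; ++i2) {
      double* dp = dst + i1lo + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      const double* sp = src + (i1lo + d1) +
        (R_xlen_t)n1 * ((i2 + d2) + (R_xlen_t)n2 * (i3 + d3));
      for (int i = 0; i < len; ++i) dp[i] += wv * sp[i];
    }
  }
}

static double dot_shift(const double* a, const double* b,
                        int d1, int d2, int d3, int n1, int n2, int n3) {
  // sum over i of a[i + d] * b[i] on the valid range
  const int i1lo = std::max(0, -d1), i1hi = std::min(n1, n1 - d1);
  const int i2lo = std::max(0, -d2), i2hi = std::min(n2, n2 - d2);
  const int i3lo = std::max(0, -d3), i3hi = std::min(n3, n3 - d3);
  const int len = i1hi - i1lo;
  if (len <= 0) return 0.0;
  double acc = 0.0;
  for (int i3 = i3lo; i3 < i3hi; ++i3) {
    for (int i2 = i2lo; i2 < i2hi; ++i2) {
      const double* ap = a + (i1lo + d1) +
        (R_xlen_t)n1 * ((i2 + d2) + (R_xlen_t)n2 * (i3 + d3));
      const double* bp = b + i1lo + (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i = 0; i < len; ++i) acc += ap[i] * bp[i];
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector bias) {
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], cin = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  if (wd[3] != cin) stop("kernel input channels do not match volume channels");
  const int r1 = (k1 - 1) / 2, r2 = (k2 - 1) / 2, r3 = (k3 - 1) / 2;
  const R_xlen_t slab = (R_xlen_t)n1 * n2 * n3;
  NumericVector y(slab * cout);
  double* yp0 = REAL(y);
  const double* xp0 = REAL(x);
  const double* wp = REAL(w);
  for (int co = 0; co < cout; ++co) {
    double* yp = yp0 + slab * co;
    const double b = bias[co];
    for (R_xlen_t i = 0; i < slab; ++i) yp[i] = b;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xp = xp0 + slab * ci;
      for (int d3 = -r3; d3 <= r3; ++d3)
        for (int d2 = -r2; d2 <= r2; ++d2)
          for (int d1 = -r1; d1 <= r1; ++d1) {
            const R_xlen_t wi = (d1 + r1) +
              (R_xlen_t)k1 * ((d2 + r2) + (R_xlen_t)k2 * ((d3 + r3) + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)));
            accum_shift(yp, xp, wp[wi], d1, d2, d3, n1, n2, n3);
          }
    }
  }
  y.attr("dim") = IntegerVector::create(n1, n2, n3, cout);
  return y;
}

// Gradient of a scalar loss w.r.t. the convolution input, given the gradient
// dy w.r.t. the output: correlation of dy with the kernel (flipped offsets).
// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector dy, IntegerVector yd,
                                   NumericVector w, IntegerVector wd) {
  const int n1 = yd[0], n2 = yd[1], n3 = yd[2], cout = yd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], cin = wd[3];
  if (wd[4] != cout) stop("kernel output channels do not match gradient channels");
  const int r1 = (k1 - 1) / 2, r2 = (k2 - 1) / 2, r3 = (k3 - 1) / 2;
  const R_xlen_t slab = (R_xlen_t)n1 * n2 * n3;
  NumericVector dx(slab * cin);
  double* dxp0 = REAL(dx);
  const double* dyp0 = REAL(dy);
  const double* wp = REAL(w);
  for (int ci = 0; ci < cin; ++ci) {
    double* dxp = dxp0 + slab * ci;
    for (int co = 0; co < cout; ++co) {
      const double* dyp = dyp0 + slab * co;
      for (int d3 = -r3; d3 <= r3; ++d3)
        for (int d2 = -r2; d2 <= r2; ++d2)
          for (int d1 = -r1; d1 <= r1; ++d1) {
            // x[i] entered y[i + d] with kernel offset -d
            const R_xlen_t wi = (r1 - d1) +
              (R_xlen_t)k1 * ((r2 - d2) + (R_xlen_t)k2 * ((r3 - d3) + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)));
            accum_shift(dxp, dyp, wp[wi], d1, d2, d3, n1, n2, n3);
          }
    }
  }
  dx.attr("dim") = IntegerVector::create(n1, n2, n3, cin);
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_weights(NumericVector x, IntegerVector xd,
                            NumericVector dy, IntegerVector yd,
                            IntegerVector kdim) {
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], cin = xd[3];
  const int cout = yd[3];
  const int k1 = kdim[0], k2 = kdim[1], k3 = kdim[2];
  const int r1 = (k1 - 1) / 2, r2 = (k2 - 1) / 2, r3 = (k3 - 1) / 2;
  const R_xlen_t slab = (R_xlen_t)n1 * n2 * n3;
  NumericVector dw((R_xlen_t)k1 * k2 * k3 * cin * cout);
  NumericVector db(cout);
  const double* xp0 = REAL(x);
  const double* dyp0 = REAL(dy);
  double* dwp = REAL(dw);
  for (int co = 0; co < cout; ++co) {
    const double* dyp = dyp0 + slab * co;
    double bacc = 0.0;
    for (R_xlen_t i = 0; i < slab; ++i) bacc += dyp[i];
    db[co] = bacc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xp = xp0 + slab * ci;
      for (int d3 = -r3; d3 <= r3; ++d3)
        for (int d2 = -r2; d2 <= r2; ++d2)
          for (int d1 = -r1; d1 <= r1; ++d1) {
            const R_xlen_t wi = (d1 + r1) +
              (R_xlen_t)k1 * ((d2 + r2) + (R_xlen_t)k2 * ((d3 + r3) + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)));
            dwp[wi] = dot_shift(xp, dyp, d1, d2, d3, n1, n2, n3);
          }
    }
  }
  dw.attr("dim") = IntegerVector::create(k1, k2, k3, cin, cout);
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Average pooling with window 2 and stride 2 along every spatial axis whose
// extent is > 1 (so 2D volumes with n3 = 1 keep their singleton axis).
// Spatial extents > 1 must be even.
// [[Rcpp::export]]
NumericVector cpp_avgpool3d(NumericVector x, IntegerVector xd) {
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], nc = xd[3];
  const int s1 = n1 > 1 ? 2 : 1, s2 = n2 > 1 ? 2 : 1, s3 = n3 > 1 ? 2 : 1;
  if (n1 % s1 || n2 % s2 || n3 % s3) stop("pooling requires even spatial extents");
  const int m1 = n1 / s1, m2 = n2 / s2, m3 = n3 / s3;
  const double norm = 1.0 / (s1 * s2 * s3);
  NumericVector y((R_xlen_t)m1 * m2 * m3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int i3 = 0; i3 < m3; ++i3)
      for (int i2 = 0; i2 < m2; ++i2)
        for (int i1 = 0; i1 < m1; ++i1) {
          double acc = 0.0;
          for (int d3 = 0; d3 < s3; ++d3)
            for (int d2 = 0; d2 < s2; ++d2)
              for (int d1 = 0; d1 < s1; ++d1)
                acc += x[idx4(s1 * i1 + d1, s2 * i2 + d2, s3 * i3 + d3, c, n1, n2, n3)];
          y[idx4(i1, i2, i3, c, m1, m2, m3)] = acc * norm;
        }
  y.attr("dim") = IntegerVector::create(m1, m2, m3, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool3d_bwd(NumericVector dy, IntegerVector yd, IntegerVector xd) {
  const int n1 = xd[0], n2 = xd[1], n3 = xd[2], nc = xd[3];
  const int m1 = yd[0], m2 = yd[1], m3 = yd[2];
  const int s1 = n1 / m1, s2 = n2 / m2, s3 = n3 / m3;
  const double norm = 1.0 / (s1 * s2 * s3);
  NumericVector dx((R_xlen_t)n1 * n2 * n3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1)
          dx[idx4(i1, i2, i3, c, n1, n2, n3)] =
            dy[idx4(i1 / s1, i2 / s2, i3 / s3, c, m1, m2, m3)] * norm;
  dx.attr("dim") = IntegerVector::create(n1, n2, n3, nc);
  return dx;
}

// Nearest-neighbour upsampling matching cpp_avgpool3d's strides.
// [[Rcpp::export]]
NumericVector cpp_upsample_nearest(NumericVector x, IntegerVector xd, IntegerVector outd) {
  const int m1 = xd[0], m2 = xd[1], m3 = xd[2], nc = xd[3];
  const int n1 = outd[0], n2 = outd[1], n3 = outd[2];
  const int s1 = n1 / m1, s2 = n2 / m2, s3 = n3 / m3;
  NumericVector y((R_xlen_t)n1 * n2 * n3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1)
          y[idx4(i1, i2, i3, c, n1, n2, n3)] =
            x[idx4(i1 / s1, i2 / s2, i3 / s3, c, m1, m2, m3)];
  y.attr("dim") = IntegerVector::create(n1, n2, n3, nc);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_nearest_bwd(NumericVector dy, IntegerVector yd, IntegerVector xd) {
  const int m1 = xd[0], m2 = xd[1], m3 = xd[2], nc = xd[3];
  const int n1 = yd[0], n2 = yd[1], n3 = yd[2];
  const int s1 = n1 / m1, s2 = n2 / m2, s3 = n3 / m3;
  NumericVector dx((R_xlen_t)m1 * m2 * m3 * nc);
  for (int c = 0; c < nc; ++c)
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1)
          dx[idx4(i1 / s1, i2 / s2, i3 / s3, c, m1, m2, m3)] +=
            dy[idx4(i1, i2, i3, c, n1, n2, n3)];
  dx.attr("dim") = IntegerVector::create(m1, m2, m3, nc);
  return dx;
}

// Connected-component labelling with 6/18/26-connectivity.
// 18-connectivity = offsets with at most two non-zero coordinates
// (faces + edges, corners excluded). Labels are assigned in the order the
// first voxel of each component is met in column-major scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector md, int connectivity) {
  const int n1 = md[0], n2 = md[1], n3 = md[2];
  std::vector<int> off1, off2, off3;
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        const int nz = (d1 != 0) + (d2 != 0) + (d3 != 0);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        off1.push_back(d1); off2.push_back(d2); off3.push_back(d3);
      }
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      const int cur = q.front(); q.pop();
      const int i1 = cur % n1, i2 = (cur / n1) % n2, i3 = cur / (n1 * n2);
      for (size_t k = 0; k < off1.size(); ++k) {
        const int j1 = i1 + off1[k], j2 = i2 + off2[k], j3 = i3 + off3[k];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
        const int j = j1 + n1 * (j2 + n2 * j3);
        if (mask[j] != 0 && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(n1, n2, n3);
  return lab;
}

// Row-wise signed maximum-magnitude reduction: for each row of G return the
// entry of largest absolute value keeping its sign; ties go to the smallest
// column index (columns are ordered by scan order of the source voxels).
// [[Rcpp::export]]
NumericVector cpp_signed_absmax_rows(NumericMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = G(i, 0), besta = std::fabs(G(i, 0));
    for (int j = 1; j < m; ++j) {
      const double a = std::fabs(G(i, j));
      if (a > besta) { besta = a; best = G(i, j); }
    }
    out[i] = best;
  }
  return out;
}
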