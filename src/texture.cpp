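#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D directions (half of the 26-neighbourhood)
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector vol, IntegerVector dims, int nlev) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nlev, nlev);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int g = vol[lin(i, j, k, nx, ny)];
        if (g == NA_INTEGER) continue;
        int i2 = i + dx, j2 = j + dy, k2 = k + dz;
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
          continue;
        int g2 = vol[lin(i2, j2, k2, nx, ny)];
        if (g2 == NA_INTEGER) continue;
        M(g - 1, g2 - 1) += 1.0;  // symmetric: count both orders
        M(g2 - 1, g - 1) += 1.0;
      }
  }
  return M;
}

// run-length matrix summed over the 13 directions; columns = run length
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector vol, IntegerVector dims, int nlev) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxlen = nx + ny + nz;
  NumericMatrix M(nlev, maxlen);
  int used = 1;
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int g = vol[lin(i, j, k, nx, ny)];
        if (g == NA_INTEGER) continue;
        // run start: predecessor along -d absent or different
        int ip = i - dx, jp = j - dy, kp = k - dz;
        if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz) {
          int gp = vol[lin(ip, jp, kp, nx, ny)];
          if (gp == g) continue;
        }
        int len = 1;
        int i2 = i + dx, j2 = j + dy, k2 = k + dz;
        while (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny && k2 >= 0 && k2 < nz
               && vol[lin(i2, j2, k2, nx, ny)] == g) {
          ++len; i2 += dx; j2 += dy; k2 += dz;
        }
        M(g - 1, len - 1) += 1.0;
        if (len > used) used = len;
      }
  }
  return M(Range(0, nlev - 1), Range(0, used - 1));
}

// size-zone matrix: zones are 26-connected components of equal gray level
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector vol, IntegerVector dims, int nlev) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  int maxsize = 1;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int p0 = lin(i, j, k, nx, ny);
      int g = vol[p0];
      if (g == NA_INTEGER || seen[p0]) continue;
      int size = 0;
      std::queue<int> q;
      q.push(p0); seen[p0] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        ++size;
        int ci = p % nx, cj = (p / nx) % ny, ck = p / (nx * ny);
        for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int i2 = ci + dx, j2 = cj + dy, k2 = ck + dz;
            if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
              continue;
            int p2 = lin(i2, j2, k2, nx, ny);
            if (!seen[p2] && vol[p2] == g) { seen[p2] = 1; q.push(p2); }
          }
      }
      zones.push_back(std::make_pair(g, size));
      if (size > maxsize) maxsize = size;
    }
  NumericMatrix M(nlev, maxsize);
  for (size_t z = 0; z < zones.size(); ++z)
    M(zones[z].first - 1, zones[z].second - 1) += 1.0;
  return M;
}

// NGTDM: per level, count n_i and s_i = sum |g - mean(available neighbours)|
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector vol, IntegerVector dims, int nlev) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(nlev, 2);  // columns: n_i, s_i
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int g = vol[lin(i, j, k, nx, ny)];
      if (g == NA_INTEGER) continue;
      double sum = 0.0; int cnt = 0;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue;
          int g2 = vol[lin(i2, j2, k2, nx, ny)];
          if (g2 == NA_INTEGER) continue;
          sum += g2; ++cnt;
        }
      if (cnt == 0) continue;  // isolated voxel: no valid neighbourhood
      out(g - 1, 0) += 1.0;
      out(g - 1, 1) += std::fabs((double)g - sum / cnt);
    }
  return out;
}

// dependence matrix: dep = 1 + number of 26-neighbours with equal level
// (alpha = 0; the centre voxel counts in its own dependence)
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector vol, IntegerVector dims, int nlev) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nlev, 27);
  int used = 1;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int g = vol[lin(i, j, k, nx, ny)];
      if (g == NA_INTEGER) continue;
      int dep = 1;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
            continue;
          if (vol[lin(i2, j2, k2, nx, ny)] == g) ++dep;
        }
      M(g - 1, dep - 1) += 1.0;
      if (dep > used) used = dep;
    }
  return M(Range(0, nlev - 1), Range(0, used - 1));
}

// symmetric (half-sample) boundary reflection
static inline int reflect(int t, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  t %= period; if (t < 0) t += period;
  return (t < n) ? t : period - 1 - t;
}

// separable 3D convolution with per-axis kernels (centred, symmetric padding)
// [[Rcpp::export]]
NumericVector cpp_conv3_sep(NumericVector vol, IntegerVector dims,
                            NumericVector fx, NumericVector fy,
                            NumericVector fz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  NumericVector a(vol), b(n);
  const NumericVector *flt[3] = {&fx, &fy, &fz};
  for (int ax = 0; ax < 3; ++ax) {
    const NumericVector &f = *flt[ax];
    int m = f.size(), half = m / 2;
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int t = 0; t < m; ++t) {
          int off = t - half;
          int i2 = i, j2 = j, k2 = k;
          if (ax == 0) i2 = reflect(i + off, nx);
          else if (ax == 1) j2 = reflect(j + off, ny);
          else k2 = reflect(k + off, nz);
          s += f[t] * a[lin(i2, j2, k2, nx, ny)];
        }
        b[lin(i, j, k, nx, ny)] = s;
      }
    std::swap(a, b);
  }
  return a;
}

static double mcc_from_counts(double tp, double tn, double fp, double fn) {
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0.0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(den);
}

// fold-averaged MCC for every feature pair under a 2-class LDA with pooled
// covariance, per-fold z-scoring from the training split only.
// X: n x p, y in {0,1}, fold in 1..K. Returns C(p,2) scores in the order of
// pairs (a,b), a < b, a-major (same order as utils::combn).
// [[Rcpp::export]]
NumericVector cpp_pair_scores_lda(NumericMatrix X, IntegerVector y,
                                  IntegerVector fold, int K) {
  int n = X.nrow(), p = X.ncol();
  int npair = p * (p - 1) / 2;
  NumericVector score(npair, 0.0);
  std::vector<double> Z(n * p);
  for (int k = 1; k <= K; ++k) {
    // per-fold standardization of all columns from the training split
    for (int c = 0; c < p; ++c) {
      double mu = 0.0; int ntr = 0;
      for (int r = 0; r < n; ++r)
        if (fold[r] != k) { mu += X(r, c); ++ntr; }
      mu /= ntr;
      double ss = 0.0;
      for (int r = 0; r < n; ++r)
        if (fold[r] != k) { double d = X(r, c) - mu; ss += d * d; }
      double sd = (ntr > 1) ? std::sqrt(ss / (ntr - 1)) : 1.0;
      if (sd <= 0.0) sd = 1.0;
      for (int r = 0; r < n; ++r) Z[c * n + r] = (X(r, c) - mu) / sd;
    }
    int idx = 0;
    for (int a = 0; a < p - 1; ++a) for (int b = a + 1; b < p; ++b, ++idx) {
      const double *xa = &Z[a * n], *xb = &Z[b * n];
      // class means and pooled covariance on the training split
      double m0a = 0, m0b = 0, m1a = 0, m1b = 0; int n0 = 0, n1 = 0;
      for (int r = 0; r < n; ++r) {
        if (fold[r] == k) continue;
        if (y[r] == 1) { m1a += xa[r]; m1b += xb[r]; ++n1; }
        else           { m0a += xa[r]; m0b += xb[r]; ++n0; }
      }
      m0a /= n0; m0b /= n0; m1a /= n1; m1b /= n1;
      double saa = 0, sab = 0, sbb = 0;
      for (int r = 0; r < n; ++r) {
        if (fold[r] == k) continue;
        double da = xa[r] - (y[r] == 1 ? m1a : m0a);
        double db = xb[r] - (y[r] == 1 ? m1b : m0b);
        saa += da * da; sab += da * db; sbb += db * db;
      }
      double dof = n0 + n1 - 2;
      saa /= dof; sab /= dof; sbb /= dof;
      double det = saa * sbb - sab * sab;
      if (det < 1e-12) { saa += 1e-6; sbb += 1e-6; det = saa * sbb - sab * sab; }
      double dma = m1a - m0a, dmb = m1b - m0b;
      double wa = ( sbb * dma - sab * dmb) / det;
      double wb = (-sab * dma + saa * dmb) / det;
      double thr = 0.5 * (wa * (m0a + m1a) + wb * (m0b + m1b));
      double tp = 0, tn = 0, fp = 0, fn = 0;
      for (int r = 0; r < n; ++r) {
        if (fold[r] != k) continue;
        int pred = (wa * xa[r] + wb * xb[r] > thr) ? 1 : 0;
        if (y[r] == 1) { if (pred == 1) ++tp; else ++fn; }
        else           { if (pred == 0) ++tn; else ++fp; }
      }
      score[idx] += mcc_from_counts(tp, tn, fp, fn);
    }
  }
  for (int i = 0; i < npair; ++i) score[i] /= K;
  return score;
}
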