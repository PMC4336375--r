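#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact k-nearest-neighbour searches under the rigid-body configuration
// metrics.  Brute force O(n^2): the estimators require exact neighbours
// (approximate search biases the distance distribution), and the mixed
// translation/rotation metric rules out standard KD-trees.  The inner loop
// prunes with acos(x) >= sqrt(2(1-x)) on [0,1], so the expensive acos is
// only evaluated for genuine candidates.

static inline double rot_angle(double adot) {
  if (adot > 1.0) adot = 1.0;
  return 2.0 * std::acos(adot);
}

// insert squared distance into ascending best[0..k-1]
static inline void heap_insert(double *best, int k, double d2) {
  if (d2 >= best[k - 1]) return;
  int j = k - 1;
  while (j > 0 && best[j - 1] > d2) {
    best[j] = best[j - 1];
    --j;
  }
  best[j] = d2;
}

// [[Rcpp::export]]
NumericMatrix knn_rigid_cpp(NumericMatrix pos, NumericMatrix quat, int k) {
  const int n = pos.nrow();
  if (quat.nrow() != n) stop("pos and quat must have the same number of rows");
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericMatrix out(n, k);
  const double *px = &pos(0, 0), *py = px + n, *pz = py + n;
  const double *qw = &quat(0, 0), *qx = qw + n, *qy = qx + n, *qz = qy + n;
  std::vector<double> best(k);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), inf);
    double worst = inf;
    const double xi = px[i], yi = py[i], zi = pz[i];
    const double wi = qw[i], ai = qx[i], bi = qy[i], ci = qz[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = px[j] - xi, dy = py[j] - yi, dz = pz[j] - zi;
      const double dt2 = dx * dx + dy * dy + dz * dz;
      if (dt2 >= worst) continue;
      double adot = std::fabs(wi * qw[j] + ai * qx[j] + bi * qy[j] + ci * qz[j]);
      // d_orient >= 2*sqrt(2(1-|dot|)): cheap lower bound before acos
      if (dt2 + 8.0 * (1.0 - adot) >= worst) continue;
      const double ang = rot_angle(adot);
      const double d2 = dt2 + ang * ang;
      if (d2 < worst) {
        heap_insert(best.data(), k, d2);
        worst = best[k - 1];
      }
    }
    for (int m = 0; m < k; ++m) out(i, m) = std::sqrt(best[m]);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix knn_rigid_pair_cpp(NumericMatrix posA, NumericMatrix quatA,
                                 NumericMatrix posB, NumericMatrix quatB,
                                 int k) {
  const int n = posA.nrow();
  if (posB.nrow() != n || quatA.nrow() != n || quatB.nrow() != n)
    stop("all pose arrays must have the same number of rows");
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericMatrix out(n, k);
  const double *ax = &posA(0, 0), *ay = ax + n, *az = ay + n;
  const double *aw = &quatA(0, 0), *aq1 = aw + n, *aq2 = aq1 + n, *aq3 = aq2 + n;
  const double *bx = &posB(0, 0), *by = bx + n, *bz = by + n;
  const double *bw = &quatB(0, 0), *bq1 = bw + n, *bq2 = bq1 + n, *bq3 = bq2 + n;
  std::vector<double> best(k);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), inf);
    double worst = inf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = ax[j] - ax[i], dy = ay[j] - ay[i], dz = az[j] - az[i];
      double dt2 = dx * dx + dy * dy + dz * dz;
      dx = bx[j] - bx[i]; dy = by[j] - by[i]; dz = bz[j] - bz[i];
      dt2 += dx * dx + dy * dy + dz * dz;
      if (dt2 >= worst) continue;
      double adotA = std::fabs(aw[i] * aw[j] + aq1[i] * aq1[j] +
                               aq2[i] * aq2[j] + aq3[i] * aq3[j]);
      double adotB = std::fabs(bw[i] * bw[j] + bq1[i] * bq1[j] +
                               bq2[i] * bq2[j] + bq3[i] * bq3[j]);
      if (dt2 + 8.0 * (2.0 - adotA - adotB) >= worst) continue;
      const double angA = rot_angle(adotA), angB = rot_angle(adotB);
      const double d2 = dt2 + angA * angA + angB * angB;
      if (d2 < worst) {
        heap_insert(best.data(), k, d2);
        worst = best[k - 1];
      }
    }
    for (int m = 0; m < k; ++m) out(i, m) = std::sqrt(best[m]);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix knn_euclidean_cpp(NumericMatrix x, int k) {
  const int n = x.nrow(), p = x.ncol();
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  NumericMatrix out(n, k);
  const double *xp = &x(0, 0);
  std::vector<double> best(k);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    std::fill(best.begin(), best.end(), inf);
    double worst = inf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0.0;
      for (int c = 0; c < p; ++c) {
        const double d = xp[c * n + j] - xp[c * n + i];
        d2 += d * d;
        if (d2 >= worst) break;
      }
      if (d2 < worst) {
        heap_insert(best.data(), k, d2);
        worst = best[k - 1];
      }
    }
    for (int m = 0; m < k; ++m) out(i, m) = std::sqrt(best[m]);
  }
  return out;
}
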