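#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Distances are floored at 1e-12 so that downstream log() calls stay finite
// when duplicate points occur.
static const double DIST_FLOOR2 = 1e-24;  // squared-distance floor

// Copy an n x d column-major R matrix into point-major (row-contiguous)
// storage for cache-friendly pairwise scans.
static std::vector<double> point_major(const NumericMatrix& m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<double> out(static_cast<size_t>(n) * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      out[static_cast<size_t>(i) * d + j] = m(i, j);
  return out;
}

static inline double sqdist(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    const double diff = a[c] - b[c];
    s += diff * diff;
  }
  return s;
}

// Running "k-th smallest" tracker: a small max-array of the k best squared
// distances seen so far (k is 1 in the default MIND configuration).
struct KBest {
  std::vector<double> best;
  void init(int k) { best.assign(k, R_PosInf); }
  inline void offer(double v) {
    double* w = &*std::max_element(best.begin(), best.end());
    if (v < *w) *w = v;
  }
  inline double kth() const {
    return *std::max_element(best.begin(), best.end());
  }
};

// k-th nearest-neighbour Euclidean distances from each row of `query` to the
// rows of `ref`. When exclude_self is true the two matrices are assumed to be
// the same point set and the i-th reference point is skipped for query i.
// [[Rcpp::export(name = ".knn_kth_dist")]]
NumericVector knn_kth_dist(NumericMatrix query, NumericMatrix ref, int k,
                           bool exclude_self) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch between query and reference");
  const int avail = exclude_self ? nr - 1 : nr;
  if (k < 1 || k > avail) stop("k out of range for reference sample size");

  std::vector<double> Q = point_major(query), Rf = point_major(ref);
  NumericVector out(nq);
  KBest kb;
  for (int i = 0; i < nq; ++i) {
    kb.init(k);
    const double* qi = &Q[static_cast<size_t>(i) * d];
    for (int j = 0; j < nr; ++j) {
      if (exclude_self && j == i) continue;
      kb.offer(sqdist(qi, &Rf[static_cast<size_t>(j) * d], d));
    }
    out[i] = std::sqrt(std::max(kb.kth(), DIST_FLOOR2));
  }
  return out;
}

// Full MIND similarity matrix over regions in one pass. `features` holds all
// vertices (points x d) grouped by region; `sizes` gives each region's vertex
// count in order. Per-point self-NN distances (rho) are computed once per
// region; each region pair is scanned once, updating the cross-NN minima of
// both directions simultaneously. Returns the symmetric R x R matrix of
// 1 / (1 + D(A||B) + D(B||A)) with zero diagonal; KL estimates are the k-NN
// estimator (d/n_a) * sum log(nu/rho) + log(n_b/(n_a-1)), clipped at 0.
// [[Rcpp::export(name = ".mind_matrix_cpp")]]
NumericMatrix mind_matrix_cpp(NumericMatrix features, IntegerVector sizes,
                              int k) {
  const int d = features.ncol(), R = sizes.size();
  std::vector<double> pts = point_major(features);
  std::vector<size_t> offset(R + 1, 0);
  for (int r = 0; r < R; ++r) {
    if (sizes[r] <= k)
      stop("region %d has too few vertices for k = %d", r + 1, k);
    offset[r + 1] = offset[r] + sizes[r];
  }
  const size_t n_total = offset[R];
  if (static_cast<size_t>(features.nrow()) != n_total)
    stop("region sizes do not sum to the number of vertices");

  // sum of log rho_k within each region (self-NN, self excluded)
  std::vector<double> sum_log_rho(R, 0.0);
  KBest kb;
  for (int r = 0; r < R; ++r) {
    const size_t o = offset[r];
    const int n = sizes[r];
    for (int i = 0; i < n; ++i) {
      kb.init(k);
      const double* qi = &pts[(o + i) * d];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        kb.offer(sqdist(qi, &pts[(o + j) * d], d));
      }
      sum_log_rho[r] += 0.5 * std::log(std::max(kb.kth(), DIST_FLOOR2));
    }
  }

  NumericMatrix M(R, R);
  std::vector<std::vector<double>> bestA, bestB;
  for (int ra = 0; ra < R - 1; ++ra) {
    const int na = sizes[ra];
    const size_t oa = offset[ra];
    for (int rb = ra + 1; rb < R; ++rb) {
      const int nb = sizes[rb];
      const size_t ob = offset[rb];
      bestA.assign(na, std::vector<double>(k, R_PosInf));
      bestB.assign(nb, std::vector<double>(k, R_PosInf));
      for (int i = 0; i < na; ++i) {
        const double* ai = &pts[(oa + i) * d];
        std::vector<double>& ba = bestA[i];
        for (int j = 0; j < nb; ++j) {
          const double s = sqdist(ai, &pts[(ob + j) * d], d);
          double* wa = &*std::max_element(ba.begin(), ba.end());
          if (s < *wa) *wa = s;
          std::vector<double>& bb = bestB[j];
          double* wb = &*std::max_element(bb.begin(), bb.end());
          if (s < *wb) *wb = s;
        }
      }
      double sum_log_nu_a = 0.0, sum_log_nu_b = 0.0;
      for (int i = 0; i < na; ++i)
        sum_log_nu_a += 0.5 * std::log(std::max(
            *std::max_element(bestA[i].begin(), bestA[i].end()), DIST_FLOOR2));
      for (int j = 0; j < nb; ++j)
        sum_log_nu_b += 0.5 * std::log(std::max(
            *std::max_element(bestB[j].begin(), bestB[j].end()), DIST_FLOOR2));
      double d_ab = (static_cast<double>(d) / na) *
                        (sum_log_nu_a - sum_log_rho[ra]) +
                    std::log(static_cast<double>(nb) / (na - 1));
      double d_ba = (static_cast<double>(d) / nb) *
                        (sum_log_nu_b - sum_log_rho[rb]) +
                    std::log(static_cast<double>(na) / (nb - 1));
      if (d_ab < 0) d_ab = 0;
      if (d_ba < 0) d_ba = 0;
      const double sim = 1.0 / (1.0 + d_ab + d_ba);
      M(ra, rb) = sim;
      M(rb, ra) = sim;
    }
  }
  return M;
}
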