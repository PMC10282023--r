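#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Statistics are evaluated on the pooled sample sorted in ascending circular
// order; a group assignment is the set of sorted-order positions belonging to
// sample 1. All four statistics below are set functions of that position set,
// and positions are always processed in ascending order so that re-drawing an
// identical assignment reproduces the observed statistic bit-for-bit.

static const double TWOPI = 2.0 * M_PI;

// a, b are pre-wrapped into [0, 2*pi), so |a - b| < 2*pi and no further
// modular reduction is needed.
static inline double geodist(double a, double b) {
  double d = std::fabs(a - b);
  return d > M_PI ? TWOPI - d : d;
}

// ART statistic G = sum of geodesic distances over cross pairs, computed from
// the precomputed distance matrix via G = sum_{i in A} rowsum_i - 2 * W_A,
// where A is sample 1's position set and W_A its within-set pair sum.
static double art_from_subset(const std::vector<double> &D,
                              const std::vector<double> &rowsum,
                              const int *pos, int m, int T) {
  double acc = 0.0, within = 0.0;
  for (int i = 0; i < m; ++i) acc += rowsum[pos[i]];
  for (int i = 0; i < m; ++i) {
    const double *row = &D[(size_t)pos[i] * T];
    for (int j = i + 1; j < m; ++j) within += row[pos[j]];
  }
  return acc - 2.0 * within;
}

// Watson two-sample U2 from the pooled-order label scan:
// d_k = F1(k) - F2(k); U2 = (m n / T^2) * sum_k (d_k - dbar)^2.
static double wu2_from_labels(const std::vector<int> &is1, int m, int n) {
  int T = m + n;
  double c1 = 0.0, c2 = 0.0, s = 0.0, s2 = 0.0;
  for (int k = 0; k < T; ++k) {
    if (is1[k]) c1 += 1.0; else c2 += 1.0;
    double d = c1 / m - c2 / n;
    s += d;
    s2 += d * d;
  }
  double dbar = s / T;
  return ((double)m * n / ((double)T * T)) * (s2 - T * dbar * dbar);
}

// Watson-Wheeler uniform-scores statistic with exact permutation variance:
// W = 2 (T-1) (C1^2 + S1^2) / (m n), asymptotically chi^2_2.
static double ww_from_subset(const std::vector<double> &cs,
                             const std::vector<double> &sn,
                             const int *pos, int m, int n) {
  double C = 0.0, S = 0.0;
  for (int i = 0; i < m; ++i) { C += cs[pos[i]]; S += sn[pos[i]]; }
  int T = m + n;
  return 2.0 * (T - 1) * (C * C + S * S) / ((double)m * n);
}

// Rao spacing-frequencies discrepancy: the m arcs between consecutive circular
// order statistics of sample 1 receive f_1..f_m sample-2 points; the statistic
// is sum_i |f_i - n/m|. pos must be ascending sorted positions of sample 1.
static double rsf_from_subset(const int *pos, int m, int n, int T) {
  double expect = (double)n / m, acc = 0.0;
  for (int i = 0; i + 1 < m; ++i) {
    int f = pos[i + 1] - pos[i] - 1;
    acc += std::fabs(f - expect);
  }
  int fwrap = (T - 1 - pos[m - 1]) + pos[0];
  acc += std::fabs(fwrap - expect);
  return acc;
}

// Runs the permutation test for any subset of the four permutation statistics
// in one pass over a shared stream of random relabellings.
//
// xs:   pooled angles sorted ascending (radians, wrapped)
// lab1: logical, TRUE where the sorted position belongs to sample 1 (observed)
// pos_of_orig: 0-based sorted position of each ORIGINAL pooled index.
//   Relabellings are drawn as subsets of original indices and mapped through
//   this vector, so the permutation stream (and hence the fixed-seed p-value)
//   is invariant under a common rotation of both samples.
// nperm: number of random relabellings
// do_*: which statistics to evaluate
//
// Returns observed statistics and exceedance counts Q (# permutations with
// statistic >= observed, up to a 1e-9 relative tolerance that counts
// mathematically tied relabellings as exceedances). Uses R's RNG: seed with
// set.seed() before calling.
// [[Rcpp::export]]
List perm_engine_cpp(NumericVector xs, LogicalVector lab1,
                     IntegerVector pos_of_orig, int nperm,
                     bool do_art, bool do_wu2, bool do_ww, bool do_rsf) {
  int T = xs.size();
  int m = 0;
  for (int i = 0; i < T; ++i) if (lab1[i]) ++m;
  int n = T - m;
  if (pos_of_orig.size() != T) stop("pos_of_orig must have length m + n");
  if (m < 1 || n < 1) stop("both samples must be non-empty");
  if (nperm < 1) stop("nperm must be >= 1");

  std::vector<double> D, rowsum, cs, sn;
  if (do_art) {
    D.assign((size_t)T * T, 0.0);
    rowsum.assign(T, 0.0);
    for (int i = 0; i < T; ++i) {
      for (int j = i + 1; j < T; ++j) {
        double d = geodist(xs[i], xs[j]);
        D[(size_t)i * T + j] = d;
        D[(size_t)j * T + i] = d;
      }
    }
    for (int i = 0; i < T; ++i) {
      double s = 0.0;
      for (int j = 0; j < T; ++j) s += D[(size_t)i * T + j];
      rowsum[i] = s;
    }
  }
  if (do_ww) {
    cs.resize(T); sn.resize(T);
    for (int k = 0; k < T; ++k) {
      double beta = TWOPI * (k + 1) / T;  // uniform scores from ranks 1..T
      cs[k] = std::cos(beta);
      sn[k] = std::sin(beta);
    }
  }

  // observed
  std::vector<int> pos1;
  pos1.reserve(m);
  for (int i = 0; i < T; ++i) if (lab1[i]) pos1.push_back(i);
  std::vector<int> is1obs(T, 0);
  for (int i = 0; i < m; ++i) is1obs[pos1[i]] = 1;

  double obs_art = do_art ? art_from_subset(D, rowsum, pos1.data(), m, T) : NA_REAL;
  double obs_wu2 = do_wu2 ? wu2_from_labels(is1obs, m, n) : NA_REAL;
  double obs_ww  = do_ww  ? ww_from_subset(cs, sn, pos1.data(), m, n) : NA_REAL;
  double obs_rsf = do_rsf ? rsf_from_subset(pos1.data(), m, n, T) : NA_REAL;

  // exceedance thresholds: ties within floating noise count as >=
  double thr_art = obs_art - 1e-9 * (std::fabs(obs_art) + 1.0);
  double thr_wu2 = obs_wu2 - 1e-9 * (std::fabs(obs_wu2) + 1.0);
  double thr_ww  = obs_ww  - 1e-9 * (std::fabs(obs_ww) + 1.0);
  double thr_rsf = obs_rsf - 1e-9 * (std::fabs(obs_rsf) + 1.0);

  long q_art = 0, q_wu2 = 0, q_ww = 0, q_rsf = 0;
  std::vector<int> idx(T), sub(m), is1(T);
  for (int i = 0; i < T; ++i) idx[i] = i;

  for (int p = 0; p < nperm; ++p) {
    // partial Fisher-Yates over ORIGINAL indices: first m entries of idx
    // become a uniform m-subset of the pooled sample
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (T - i));
      if (j >= T) j = T - 1;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < m; ++i) sub[i] = pos_of_orig[idx[i]];
    std::sort(sub.begin(), sub.end());

    if (do_art) {
      if (art_from_subset(D, rowsum, sub.data(), m, T) >= thr_art) ++q_art;
    }
    if (do_wu2) {
      std::fill(is1.begin(), is1.end(), 0);
      for (int i = 0; i < m; ++i) is1[sub[i]] = 1;
      if (wu2_from_labels(is1, m, n) >= thr_wu2) ++q_wu2;
    }
    if (do_ww) {
      if (ww_from_subset(cs, sn, sub.data(), m, n) >= thr_ww) ++q_ww;
    }
    if (do_rsf) {
      if (rsf_from_subset(sub.data(), m, n, T) >= thr_rsf) ++q_rsf;
    }
  }

  return List::create(
    _["m"] = m, _["n"] = n, _["n_permutations"] = nperm,
    _["observed"] = NumericVector::create(
      _["ART"] = obs_art, _["WU2"] = obs_wu2,
      _["WW"] = obs_ww, _["Rsf"] = obs_rsf),
    _["n_exceeding"] = NumericVector::create(
      _["ART"] = (double)q_art, _["WU2"] = (double)q_wu2,
      _["WW"] = (double)q_ww, _["Rsf"] = (double)q_rsf));
}
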