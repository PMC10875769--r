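#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Lloyd's algorithm from given initial centers. Deterministic given inputs.
// [[Rcpp::export]]
List cpp_kmeans_lloyd(const NumericMatrix& x, NumericMatrix centers,
                      int max_iter) {
  const int n = x.nrow(), d = x.ncol(), k = centers.nrow();
  IntegerVector lab(n);
  std::vector<int> cnt(k);
  NumericMatrix cen(clone(centers));
  double prev = R_PosInf, wss = 0.0;

  for (int iter = 0; iter < max_iter; ++iter) {
    wss = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bi = 0;
      for (int c = 0; c < k; ++c) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          const double diff = x(i, j) - cen(c, j);
          s += diff * diff;
        }
        if (s < best) { best = s; bi = c; }
      }
      lab[i] = bi;
      wss += best;
    }
    NumericMatrix newc(k, d);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      cnt[lab[i]]++;
      for (int j = 0; j < d; ++j) newc(lab[i], j) += x(i, j);
    }
    for (int c = 0; c < k; ++c) {
      if (cnt[c] == 0) {
        // empty cluster: reseed at the point farthest from its center
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = 0; j < d; ++j) {
            const double diff = x(i, j) - cen(lab[i], j);
            s += diff * diff;
          }
          if (s > fd) { fd = s; far = i; }
        }
        for (int j = 0; j < d; ++j) newc(c, j) = x(far, j);
      } else {
        for (int j = 0; j < d; ++j) newc(c, j) /= cnt[c];
      }
    }
    cen = newc;
    if (prev - wss < 1e-12 * (prev + 1.0)) break;
    prev = wss;
  }
  // final assignment against converged centers
  wss = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < k; ++c) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x(i, j) - cen(c, j);
        s += diff * diff;
      }
      if (s < best) { best = s; bi = c; }
    }
    lab[i] = bi + 1;
    wss += best;
  }
  return List::create(_["labels"] = lab, _["wss"] = wss, _["centers"] = cen);
}

namespace {

// PAM BUILD + SWAP on a contiguous n x n dissimilarity buffer.
void pam_core(const double* sub, int n, int k, int max_iter,
              std::vector<int>& med, std::vector<int>& lab,
              std::vector<double>* cost_trace) {
  auto D = [&](int a, int b) -> double { return sub[(size_t)b * n + a]; };
  med.clear();
  med.reserve(k);
  std::vector<char> is_med(n, 0);
  {
    double best = R_PosInf;
    int bi = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double* col = sub + (size_t)i * n;
      for (int j = 0; j < n; ++j) s += col[j];
      if (s < best) { best = s; bi = i; }
    }
    med.push_back(bi);
    is_med[bi] = 1;
  }
  std::vector<double> dnear(n);
  for (int j = 0; j < n; ++j) dnear[j] = D(j, med[0]);
  while ((int)med.size() < k) {
    double best = -1.0;
    int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (is_med[i]) continue;
      double gain = 0.0;
      const double* col = sub + (size_t)i * n;
      for (int j = 0; j < n; ++j) {
        const double g = dnear[j] - col[j];
        if (g > 0) gain += g;
      }
      if (gain > best) { best = gain; bi = i; }
    }
    med.push_back(bi);
    is_med[bi] = 1;
    for (int j = 0; j < n; ++j)
      if (D(j, bi) < dnear[j]) dnear[j] = D(j, bi);
  }

  auto total_cost = [&]() {
    double c = 0.0;
    for (int j = 0; j < n; ++j) {
      double b = R_PosInf;
      for (int mi : med) b = std::min(b, D(j, mi));
      c += b;
    }
    return c;
  };
  if (cost_trace) cost_trace->push_back(total_cost());

  std::vector<double> d1(n), d2(n);
  std::vector<int> n1(n);
  for (int iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < n; ++j) {
      d1[j] = R_PosInf;
      d2[j] = R_PosInf;
      n1[j] = -1;
    }
    for (int mi = 0; mi < k; ++mi) {
      const double* col = sub + (size_t)med[mi] * n;
      for (int j = 0; j < n; ++j) {
        const double dd = col[j];
        if (dd < d1[j]) {
          d2[j] = d1[j];
          d1[j] = dd;
          n1[j] = mi;
        } else if (dd < d2[j]) {
          d2[j] = dd;
        }
      }
    }
    // One O(n) pass per candidate h computes the swap deltas for all k
    // medoids simultaneously (the gain term is medoid-independent; the
    // loss correction only involves points whose nearest medoid is mi).
    double best_delta = -1e-12;
    int bh = -1, bm = -1;
    std::vector<double> corr(k);
    for (int h = 0; h < n; ++h) {
      if (is_med[h]) continue;
      const double* col = sub + (size_t)h * n;
      double acc0 = 0.0;
      std::fill(corr.begin(), corr.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        const double djh = col[j];
        const double gain = djh < d1[j] ? djh - d1[j] : 0.0;
        acc0 += gain;
        corr[n1[j]] += std::min(djh, d2[j]) - d1[j] - gain;
      }
      for (int mi = 0; mi < k; ++mi) {
        const double delta = acc0 + corr[mi];
        if (delta < best_delta) { best_delta = delta; bh = h; bm = mi; }
      }
    }
    if (bh < 0) break;
    is_med[med[bm]] = 0;
    med[bm] = bh;
    is_med[bh] = 1;
    if (cost_trace) cost_trace->push_back(total_cost());
  }

  lab.assign(n, 0);
  for (int j = 0; j < n; ++j) {
    double b = R_PosInf;
    int bi = 0;
    for (int mi = 0; mi < k; ++mi) {
      if (D(j, med[mi]) < b) { b = D(j, med[mi]); bi = mi; }
    }
    lab[j] = bi + 1;
  }
}

}  // namespace

// PAM (BUILD + SWAP) on a precomputed full dissimilarity matrix, restricted
// to the (1-based) rows in `idx`. Deterministic; ties broken by lowest index.
// [[Rcpp::export]]
List cpp_pam(const NumericMatrix& d, const IntegerVector& idx, int k,
             int max_iter, bool trace_cost) {
  const int n = idx.size();
  std::vector<double> sub((size_t)n * n);
  std::vector<int> ix(n);
  for (int i = 0; i < n; ++i) ix[i] = idx[i] - 1;
  for (int b = 0; b < n; ++b) {
    const double* col = &d(0, ix[b]);
    double* out = &sub[(size_t)b * n];
    for (int a = 0; a < n; ++a) out[a] = col[ix[a]];
  }
  std::vector<int> med, lab;
  std::vector<double> trace;
  pam_core(sub.data(), n, k, max_iter, med, lab,
           trace_cost ? &trace : nullptr);
  double cost = 0.0;
  for (int j = 0; j < n; ++j) {
    double b = R_PosInf;
    for (int mi : med) b = std::min(b, sub[(size_t)mi * n + j]);
    cost += b;
  }
  IntegerVector labv(n), medv(k);
  for (int mi = 0; mi < k; ++mi) medv[mi] = med[mi] + 1;
  for (int j = 0; j < n; ++j) labv[j] = lab[j];
  return List::create(_["labels"] = labv, _["medoids"] = medv,
                      _["cost"] = cost, _["cost_trace"] = wrap(trace));
}

// Full PAM consensus loop: for each column of idxmat (1-based subsample
// indices into d), gather the submatrix into a reused buffer, run PAM, and
// accumulate co-sampling / co-clustering counts in place.
// [[Rcpp::export]]
void cpp_consensus_pam(const NumericMatrix& d, const IntegerMatrix& idxmat,
                       int k, int max_iter, IntegerMatrix conn,
                       IntegerMatrix cosample) {
  const int m = idxmat.nrow();
  const int reps = idxmat.ncol();
  std::vector<double> sub((size_t)m * m);
  std::vector<int> ix(m), med, lab;
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < m; ++i) ix[i] = idxmat(i, r) - 1;
    for (int b = 0; b < m; ++b) {
      const double* col = &d(0, ix[b]);
      double* out = &sub[(size_t)b * m];
      for (int a = 0; a < m; ++a) out[a] = col[ix[a]];
    }
    pam_core(sub.data(), m, k, max_iter, med, lab, nullptr);
    for (int a = 0; a < m; ++a) {
      const int ia = ix[a];
      const int la = lab[a];
      for (int b = a + 1; b < m; ++b) {
        const int ib = ix[b];
        const int rr = ia < ib ? ia : ib;
        const int cc = ia < ib ? ib : ia;
        cosample(rr, cc)++;
        if (la == lab[b]) conn(rr, cc)++;
      }
    }
  }
}

// Euclidean distance matrix (rows of x).
// [[Rcpp::export]]
NumericMatrix cpp_euclidean(const NumericMatrix& x) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x(a, j) - x(b, j);
        s += diff * diff;
      }
      const double v = std::sqrt(s);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
  return out;
}

// Accumulate co-sampling and co-clustering counts (upper triangle, in place).
// idx: 1-based indices of the subsampled items; labels: their cluster labels.
// [[Rcpp::export]]
void cpp_consensus_accumulate(IntegerMatrix conn, IntegerMatrix cosample,
                              const IntegerVector& idx,
                              const IntegerVector& labels) {
  const int m = idx.size();
  for (int a = 0; a < m; ++a) {
    const int ia = idx[a] - 1;
    const int la = labels[a];
    for (int b = a + 1; b < m; ++b) {
      const int ib = idx[b] - 1;
      const int r = ia < ib ? ia : ib;
      const int c = ia < ib ? ib : ia;
      cosample(r, c)++;
      if (la == labels[b]) conn(r, c)++;
    }
  }
}
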