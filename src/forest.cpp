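// Compact regression forest used by the chained random-forest imputer:
// bootstrap resampling, mtry random candidate features per node, best
// variance-reduction split, mean prediction in leaves, OOB mean squared
// error tracked for the convergence test of the chained updates.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int var;       // -1 for leaf
  double val;    // split threshold (go left if x <= val)
  int left, right;
  double pred;
};

struct BuildCtx {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry;
  int min_node;
  std::mt19937& rng;
};

void build_node(std::vector<Node>& nodes, int node_id, std::vector<int>& rows,
                int lo, int hi, BuildCtx& ctx) {
  const int cnt = hi - lo;
  double s = 0.0;
  for (int i = lo; i < hi; ++i) s += ctx.y[rows[i]];
  nodes[node_id].pred = s / cnt;
  nodes[node_id].var = -1;
  if (cnt < 2 * ctx.min_node) return;

  const int p = ctx.X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), ctx.rng);
  const int m = std::min(ctx.mtry, p);

  double best_gain = 1e-12;
  int best_var = -1;
  double best_val = 0.0;

  std::vector<int> idx(rows.begin() + lo, rows.begin() + hi);
  double ts = 0.0;
  for (int i = 0; i < cnt; ++i) ts += ctx.y[idx[i]];

  for (int f = 0; f < m; ++f) {
    const int j = feats[f];
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return ctx.X(a, j) < ctx.X(b, j);
    });
    double cls = 0.0;
    for (int i = 0; i < cnt - 1; ++i) {
      cls += ctx.y[idx[i]];
      const int nl = i + 1, nr = cnt - nl;
      if (nl < ctx.min_node || nr < ctx.min_node) continue;
      if (ctx.X(idx[i], j) == ctx.X(idx[i + 1], j)) continue;
      const double crs = ts - cls;
      const double gain =
          cls * cls / nl + crs * crs / nr - ts * ts / cnt;
      if (gain > best_gain) {
        best_gain = gain;
        best_var = j;
        best_val = 0.5 * (ctx.X(idx[i], j) + ctx.X(idx[i + 1], j));
      }
    }
  }
  if (best_var < 0) return;

  const int mid = (int)(std::stable_partition(
                            rows.begin() + lo, rows.begin() + hi,
                            [&](int r) { return ctx.X(r, best_var) <= best_val; }) -
                        rows.begin());
  if (mid == lo || mid == hi) return;

  nodes[node_id].var = best_var;
  nodes[node_id].val = best_val;
  const int L = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  const int R = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  nodes[node_id].left = L;
  nodes[node_id].right = R;
  build_node(nodes, L, rows, lo, mid, ctx);
  build_node(nodes, R, rows, mid, hi, ctx);
}

double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X,
                   int row) {
  int id = 0;
  while (nodes[id].var >= 0)
    id = X(row, nodes[id].var) <= nodes[id].val ? nodes[id].left
                                                : nodes[id].right;
  return nodes[id].pred;
}

}  // namespace

// Fit a regression forest on (Xtrain, y) and predict Xpred.
// Returns predictions and the OOB mean squared error on the training rows.
// [[Rcpp::export]]
List cpp_forest_fit_predict(const NumericMatrix& Xtrain,
                            const NumericVector& y,
                            const NumericMatrix& Xpred, int num_trees,
                            int mtry, int min_node, int seed) {
  const int n = Xtrain.nrow();
  const int np = Xpred.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  NumericVector pred(np);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);

  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> rows(n);
    std::vector<char> in_bag(n, 0);
    for (int i = 0; i < n; ++i) {
      rows[i] = pick(rng);
      in_bag[rows[i]] = 1;
    }
    std::vector<Node> nodes;
    nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    BuildCtx ctx{Xtrain, y, mtry, min_node, rng};
    build_node(nodes, 0, rows, 0, n, ctx);

    for (int i = 0; i < np; ++i) pred[i] += predict_row(nodes, Xpred, i);
    for (int i = 0; i < n; ++i) {
      if (!in_bag[i]) {
        oob_sum[i] += predict_row(nodes, Xtrain, i);
        oob_cnt[i]++;
      }
    }
  }
  for (int i = 0; i < np; ++i) pred[i] /= num_trees;

  double mse = 0.0;
  int used = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      const double e = oob_sum[i] / oob_cnt[i] - y[i];
      mse += e * e;
      used++;
    }
  }
  mse = used > 0 ? mse / used : NA_REAL;
  return List::create(_["pred"] = pred, _["oob_mse"] = mse);
}
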