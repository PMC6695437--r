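// Stagewise least-squares boosting of depth-limited regression trees with
// exact greedy splits, bag subsampling, and Friedman split-improvement
// accounting. Trees are grown level-wise over pre-sorted feature orders so a
// tree costs O(p * n * depth) after one O(p * n log n) sort per fit.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;  // -1 => leaf
  double thr = 0.0;
  double value = 0.0;
  int left = -1;
  int right = -1;
  double sum = 0.0;  // residual sum over in-bag rows reaching the node
  int n = 0;
};

inline double split_gain(double sl, int nl, double st, int nt) {
  const double sr = st - sl;
  const int nr = nt - nl;
  return sl * sl / nl + sr * sr / nr - st * st / nt;
}

inline double predict_row(const std::vector<Node>& nodes, const double* x,
                          int nrow, int row) {
  int u = 0;
  while (nodes[u].feature >= 0) {
    const double v = x[static_cast<size_t>(nodes[u].feature) * nrow + row];
    u = (v <= nodes[u].thr) ? nodes[u].left : nodes[u].right;
  }
  return nodes[u].value;
}

void build_tree(const NumericMatrix& X,
                const std::vector<std::vector<int>>& order,
                const std::vector<char>& inbag,
                const std::vector<double>& resid, int max_depth, int min_node,
                std::vector<Node>& nodes, std::vector<int>& node_of,
                std::vector<double>& imp) {
  const int n = X.nrow(), p = X.ncol();
  nodes.clear();
  Node root;
  for (int i = 0; i < n; ++i)
    if (inbag[i]) {
      root.sum += resid[i];
      ++root.n;
    }
  nodes.push_back(root);
  for (int i = 0; i < n; ++i) node_of[i] = inbag[i] ? 0 : -1;

  std::vector<int> level = {0};
  for (int depth = 0; depth < max_depth && !level.empty(); ++depth) {
    const int nn = static_cast<int>(nodes.size());
    std::vector<double> best_gain(nn, 0.0), best_thr(nn, 0.0);
    std::vector<int> best_feat(nn, -1);
    std::vector<char> active(nn, 0);
    for (int u : level)
      if (nodes[u].n >= 2 * min_node) active[u] = 1;

    std::vector<int> cnt(nn);
    std::vector<double> sum(nn), lastx(nn);
    for (int j = 0; j < p; ++j) {
      std::fill(cnt.begin(), cnt.end(), 0);
      std::fill(sum.begin(), sum.end(), 0.0);
      const double* xj = &X[0] + static_cast<size_t>(j) * n;
      for (int i : order[j]) {
        const int u = node_of[i];
        if (u < 0 || u >= nn || !active[u]) continue;
        const double x = xj[i];
        if (cnt[u] >= min_node && nodes[u].n - cnt[u] >= min_node &&
            x > lastx[u]) {
          const double g = split_gain(sum[u], cnt[u], nodes[u].sum, nodes[u].n);
          if (g > best_gain[u] + 1e-12) {
            best_gain[u] = g;
            best_feat[u] = j;
            best_thr[u] = 0.5 * (lastx[u] + x);
          }
        }
        sum[u] += resid[i];
        ++cnt[u];
        lastx[u] = x;
      }
    }

    std::vector<int> next_level;
    for (int u : level) {
      if (best_feat[u] < 0) continue;
      nodes[u].feature = best_feat[u];
      nodes[u].thr = best_thr[u];
      imp[best_feat[u]] += best_gain[u];
      Node child;
      nodes[u].left = static_cast<int>(nodes.size());
      nodes.push_back(child);
      nodes[u].right = static_cast<int>(nodes.size());
      nodes.push_back(child);
      next_level.push_back(nodes[u].left);
      next_level.push_back(nodes[u].right);
    }
    if (next_level.empty()) break;
    for (int i = 0; i < n; ++i) {
      const int u = node_of[i];
      if (u < 0 || nodes[u].feature < 0) continue;
      const double v = X(i, nodes[u].feature);
      const int ch = (v <= nodes[u].thr) ? nodes[u].left : nodes[u].right;
      node_of[i] = ch;
      nodes[ch].sum += resid[i];
      ++nodes[ch].n;
    }
    level = next_level;
  }
  for (auto& nd : nodes)
    if (nd.feature < 0 && nd.n > 0) nd.value = nd.sum / nd.n;
}

}  // namespace

// [[Rcpp::export]]
List brt_boost_cpp(NumericMatrix X, NumericVector y, NumericMatrix Xtest,
                   NumericVector ytest, int n_trees, double learning_rate,
                   int max_depth, double subsample, int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol(), nt = Xtest.nrow();
  if (n < 2) stop("need at least 2 training rows");
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const double* xj = &X[0] + static_cast<size_t>(j) * n;
    std::sort(order[j].begin(), order[j].end(),
              [xj](int a, int b) { return xj[a] < xj[b]; });
  }
  const double f0 = mean(y);
  std::vector<double> Ftr(n, f0), Fte(nt, f0), resid(n);
  std::vector<double> imp(p, 0.0);
  NumericVector test_sse(n_trees);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  const int bag_n =
      std::max(1, static_cast<int>(std::floor(subsample * n + 1e-9)));
  std::vector<char> inbag(n, 1);
  std::vector<int> node_of(n);
  std::vector<Node> nodes;

  for (int m = 0; m < n_trees; ++m) {
    if (bag_n < n) {
      std::shuffle(perm.begin(), perm.end(), rng);
      std::fill(inbag.begin(), inbag.end(), 0);
      for (int t = 0; t < bag_n; ++t) inbag[perm[t]] = 1;
    }
    for (int i = 0; i < n; ++i) resid[i] = y[i] - Ftr[i];
    build_tree(X, order, inbag, resid, max_depth, min_node, nodes, node_of,
               imp);
    for (int i = 0; i < n; ++i)
      Ftr[i] += learning_rate * predict_row(nodes, &X[0], n, i);
    double sse = 0.0;
    for (int i = 0; i < nt; ++i) {
      Fte[i] += learning_rate * predict_row(nodes, &Xtest[0], nt, i);
      const double d = ytest[i] - Fte[i];
      sse += d * d;
    }
    test_sse[m] = sse;
  }
  return List::create(_["importance"] = NumericVector(imp.begin(), imp.end()),
                      _["train_pred"] = NumericVector(Ftr.begin(), Ftr.end()),
                      _["test_pred"] = NumericVector(Fte.begin(), Fte.end()),
                      _["test_sse"] = test_sse, _["init"] = f0);
}
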