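// Gradient-boosted tree ensemble with a softmax multiclass objective and
// exact greedy split search. Deliberately minimal: dense features, no
// missing values, no subsampling, second-order (Newton) leaf weights with
// L2 regularization. Per-tree, per-feature gain totals are recorded so the
// fold-averaged "mean gain per tree in which the feature was used"
// importance can be computed downstream.
//
// Determinism: split search scans features in index order and keeps the
// first strictly-better candidate, so training is reproducible bit-for-bit
// for identical inputs on the same platform.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;    // leaf weight (learning rate already applied)
  double gain = 0.0;     // split gain
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// rows of X presorted once per feature; per node we scan the global order
// and skip rows outside the node (marker stamp), so split search is O(n p)
// per node with no sorting.
struct SortCtx {
  std::vector<std::vector<int>> order; // per feature, row indices by value
  std::vector<char> in_node;           // membership stamp for current node
};

SplitResult find_split(const NumericMatrix& X, const SortCtx& ctx,
                       const std::vector<int>& rows,
                       const std::vector<double>& g,
                       const std::vector<double>& h,
                       double lambda, double min_child_weight) {
  SplitResult best;
  const int m = static_cast<int>(rows.size());
  if (m < 2) return best;

  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  const double parent_score = (G * G) / (H + lambda);

  for (int j = 0; j < X.ncol(); ++j) {
    double GL = 0.0, HL = 0.0;
    int seen = 0;
    double pend_gain = 0.0, pend_lo = 0.0; // candidate awaiting its upper value
    bool pending = false;
    for (int r : ctx.order[j]) {
      if (!ctx.in_node[r]) continue;
      const double v = X(r, j);
      if (pending && v > pend_lo) {
        if (pend_gain > best.gain + 1e-12) {
          best.gain = pend_gain;
          best.feature = j;
          best.threshold = 0.5 * (pend_lo + v);
        }
        pending = false;
      }
      GL += g[r]; HL += h[r];
      ++seen;
      if (seen < m) {
        const double GR = G - GL, HR = H - HL;
        if (HL >= min_child_weight && HR >= min_child_weight) {
          pend_gain = 0.5 * ((GL * GL) / (HL + lambda) +
                             (GR * GR) / (HR + lambda) - parent_score);
          pend_lo = v;
          pending = true;
        } else {
          pending = false;
        }
      }
    }
  }
  return best;
}

int build_node(const NumericMatrix& X, SortCtx& ctx,
               const std::vector<int>& rows,
               const std::vector<double>& g,
               const std::vector<double>& h,
               int depth, int max_depth,
               double eta, double lambda, double min_child_weight,
               std::vector<Node>& nodes) {
  const int id = static_cast<int>(nodes.size());
  nodes.push_back(Node());

  SplitResult sp;
  if (depth < max_depth) {
    for (int r : rows) ctx.in_node[r] = 1;
    sp = find_split(X, ctx, rows, g, h, lambda, min_child_weight);
    for (int r : rows) ctx.in_node[r] = 0;
  }

  if (sp.feature < 0 || sp.gain <= 0.0) {
    double G = 0.0, H = 0.0;
    for (int r : rows) { G += g[r]; H += h[r]; }
    nodes[id].value = -eta * G / (H + lambda);
    return id;
  }

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, sp.feature) <= sp.threshold) lrows.push_back(r);
    else rrows.push_back(r);
  }
  nodes[id].feature = sp.feature;
  nodes[id].threshold = sp.threshold;
  nodes[id].gain = sp.gain;
  nodes[id].left = build_node(X, ctx, lrows, g, h, depth + 1, max_depth,
                              eta, lambda, min_child_weight, nodes);
  nodes[id].right = build_node(X, ctx, rrows, g, h, depth + 1, max_depth,
                               eta, lambda, min_child_weight, nodes);
  return id;
}

double predict_tree(const std::vector<Node>& nodes, const NumericMatrix& X, int row) {
  int id = 0;
  while (nodes[id].feature >= 0)
    id = (X(row, nodes[id].feature) <= nodes[id].threshold)
             ? nodes[id].left : nodes[id].right;
  return nodes[id].value;
}

NumericMatrix tree_to_matrix(const std::vector<Node>& nodes) {
  NumericMatrix out(static_cast<int>(nodes.size()), 6);
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value", "gain");
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature + 1;  // 1-based for R, 0 => leaf
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left + 1;
    out(i, 3) = nodes[i].right + 1;
    out(i, 4) = nodes[i].value;
    out(i, 5) = nodes[i].gain;
  }
  return out;
}

std::vector<Node> matrix_to_tree(const NumericMatrix& m) {
  std::vector<Node> nodes(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    nodes[i].feature = static_cast<int>(m(i, 0)) - 1;
    nodes[i].threshold = m(i, 1);
    nodes[i].left = static_cast<int>(m(i, 2)) - 1;
    nodes[i].right = static_cast<int>(m(i, 3)) - 1;
    nodes[i].value = m(i, 4);
    nodes[i].gain = m(i, 5);
  }
  return nodes;
}

} // namespace

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                   int nrounds, double eta, int max_depth,
                   double lambda, double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double>> margin(n_classes, std::vector<double>(n, 0.0));
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;

  SortCtx ctx;
  ctx.in_node.assign(n, 0);
  ctx.order.resize(p);
  for (int j = 0; j < p; ++j) {
    ctx.order[j] = all_rows;
    const int col = j;
    std::stable_sort(ctx.order[j].begin(), ctx.order[j].end(),
                     [&X, col](int a, int b) { return X(a, col) < X(b, col); });
  }

  List trees(nrounds * n_classes);
  IntegerVector tree_class(nrounds * n_classes);
  NumericMatrix tree_gain(nrounds * n_classes, p); // per-tree per-feature gain totals

  std::vector<double> g(n), h(n), prob(n_classes);
  int t_out = 0;
  for (int round = 0; round < nrounds; ++round) {
    // softmax probabilities from current margins
    std::vector<std::vector<double>> P(n_classes, std::vector<double>(n));
    for (int i = 0; i < n; ++i) {
      double mx = margin[0][i];
      for (int k = 1; k < n_classes; ++k) mx = std::max(mx, margin[k][i]);
      double denom = 0.0;
      for (int k = 0; k < n_classes; ++k) {
        prob[k] = std::exp(margin[k][i] - mx);
        denom += prob[k];
      }
      for (int k = 0; k < n_classes; ++k) P[k][i] = prob[k] / denom;
    }

    for (int k = 0; k < n_classes; ++k) {
      for (int i = 0; i < n; ++i) {
        const double pk = P[k][i];
        g[i] = pk - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(pk * (1.0 - pk), 1e-6);
      }
      std::vector<Node> nodes;
      build_node(X, ctx, all_rows, g, h, 0, max_depth, eta, lambda,
                 min_child_weight, nodes);
      for (int i = 0; i < n; ++i)
        margin[k][i] += predict_tree(nodes, X, i);
      for (const Node& nd : nodes)
        if (nd.feature >= 0) tree_gain(t_out, nd.feature) += nd.gain;
      trees[t_out] = tree_to_matrix(nodes);
      tree_class[t_out] = k;
      ++t_out;
    }
  }

  return List::create(_["trees"] = trees,
                      _["tree_class"] = tree_class,
                      _["tree_gain"] = tree_gain);
}

// [[Rcpp::export]]
NumericMatrix gbt_margin_cpp(List trees, IntegerVector tree_class,
                             NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  NumericMatrix margin(n, n_classes);
  for (int t = 0; t < trees.size(); ++t) {
    std::vector<Node> nodes = matrix_to_tree(as<NumericMatrix>(trees[t]));
    const int k = tree_class[t];
    for (int i = 0; i < n; ++i)
      margin(i, k) += predict_tree(nodes, X, i);
  }
  return margin;
}
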