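#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Trees are stored as numeric matrices, one row per node, columns:
//   var   splitting feature (1-based; 0 marks a leaf)
//   split threshold; x <= split goes left
//   left  / right  child row indices (1-based; 0 for leaves)
//   pred  mean of the bootstrap responses reaching the node
//   n     bootstrap count reaching the node (with multiplicity)

namespace {

const double kPureTol = 1e-12;

// uniform draw on 0..n-1 through R's RNG (keeps everything seed-reproducible)
inline int rand_below(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct TreeAccum {
  std::vector<double> var, split, left, right, pred, nn;
  int add_leaf(double mean, int n) {
    var.push_back(0.0); split.push_back(0.0);
    left.push_back(0.0); right.push_back(0.0);
    pred.push_back(mean); nn.push_back(n);
    return static_cast<int>(var.size()) - 1;
  }
};

struct SplitSearch {
  double score, threshold;
  int var;
};

struct Builder {
  const double* X;   // column-major, n_all x p
  const double* y;
  int n_all, p, mtry, min_node;
  const std::vector<int>& order; // per-feature ascending sort of all rows
  std::vector<int> pool;         // feature-draw workspace
  std::vector<int> cnt;          // per-sample multiplicity in current node
  std::vector<std::pair<double, double> > buf; // (x, y) pairs, small nodes
  TreeAccum tr;

  Builder(const double* X_, const double* y_, int n_all_, int p_,
          int mtry_, int min_node_, const std::vector<int>& order_)
      : X(X_), y(y_), n_all(n_all_), p(p_), mtry(mtry_), min_node(min_node_),
        order(order_), pool(p_), cnt(n_all_, 0) {
    for (int j = 0; j < p; ++j) pool[j] = j;
    buf.reserve(n_all);
  }

  // Split criterion: minimise the summed child SSE, i.e. maximise
  // sl^2/nl + sr^2/nr.  Ties keep the earlier candidate in draw order and,
  // within a feature, the smallest threshold (ascending scans, strict >).

  // scan the global presorted order, filtering by node membership counts
  void scan_global(int j, int n, double s, SplitSearch& best) const {
    const double* col = X + static_cast<std::size_t>(j) * n_all;
    const int* ord = &order[static_cast<std::size_t>(j) * n_all];
    double sl = 0.0, prev = 0.0;
    int nl = 0;
    bool started = false;
    for (int k = 0; k < n_all; ++k) {
      const int i = ord[k];
      const int c = cnt[i];
      if (c == 0) continue;
      const double v = col[i];
      if (started && v > prev && nl > 0 && nl < n) {
        const double sr = s - sl;
        const int nr = n - nl;
        const double score = sl * sl / nl + sr * sr / nr;
        if (score > best.score) {
          best.score = score;
          best.var = j;
          best.threshold = 0.5 * (prev + v);
        }
      }
      sl += c * y[i];
      nl += c;
      prev = v;
      started = true;
    }
  }

  // gather + sort the node's own observations (cheaper for small nodes)
  void scan_local(int j, const std::vector<int>& idx, int lo, int hi,
                  double s, SplitSearch& best) {
    const double* col = X + static_cast<std::size_t>(j) * n_all;
    const int n = hi - lo;
    buf.clear();
    for (int k = lo; k < hi; ++k)
      buf.push_back(std::make_pair(col[idx[k]], y[idx[k]]));
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) return; // constant in node
    double sl = 0.0;
    for (int k = 0; k + 1 < n; ++k) {
      sl += buf[k].second;
      if (buf[k + 1].first > buf[k].first) {
        const int nl = k + 1, nr = n - nl;
        const double sr = s - sl;
        const double score = sl * sl / nl + sr * sr / nr;
        if (score > best.score) {
          best.score = score;
          best.var = j;
          best.threshold = 0.5 * (buf[k].first + buf[k + 1].first);
        }
      }
    }
  }

  // grow the subtree for idx[lo, hi); returns the node's row index
  int build(std::vector<int>& idx, int lo, int hi) {
    const int n = hi - lo;
    double s = 0.0, ss = 0.0;
    for (int k = lo; k < hi; ++k) { const double v = y[idx[k]]; s += v; ss += v * v; }
    const int me = tr.add_leaf(s / n, n);
    const double sse = ss - s * s / n;
    if (n < min_node || sse <= kPureTol * (1.0 + std::fabs(ss))) return me;

    const bool use_global = 8 * n >= n_all;
    if (use_global)
      for (int k = lo; k < hi; ++k) cnt[idx[k]]++;

    SplitSearch best;
    best.score = -1.0;
    best.var = -1;
    best.threshold = 0.0;
    for (int m = 0; m < mtry; ++m) {
      std::swap(pool[m], pool[m + rand_below(p - m)]);
      const int j = pool[m];
      if (use_global) scan_global(j, n, s, best);
      else scan_local(j, idx, lo, hi, s, best);
    }
    if (use_global)
      for (int k = lo; k < hi; ++k) cnt[idx[k]] = 0;
    if (best.var < 0) return me; // every candidate constant within the node

    const double* col = X + static_cast<std::size_t>(best.var) * n_all;
    int a = lo, b = hi - 1;
    while (a <= b) {
      if (col[idx[a]] <= best.threshold) ++a;
      else std::swap(idx[a], idx[b--]);
    }
    const int l = build(idx, lo, a);
    const int r = build(idx, a, hi);
    tr.var[me] = best.var + 1;
    tr.split[me] = best.threshold;
    tr.left[me] = l + 1;
    tr.right[me] = r + 1;
    return me;
  }
};

NumericMatrix pack(const TreeAccum& tr) {
  const int m = static_cast<int>(tr.var.size());
  NumericMatrix out(m, 6);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = tr.var[i];  out(i, 1) = tr.split[i];
    out(i, 2) = tr.left[i]; out(i, 3) = tr.right[i];
    out(i, 4) = tr.pred[i]; out(i, 5) = tr.nn[i];
  }
  colnames(out) = CharacterVector::create("var", "split", "left", "right", "pred", "n");
  return out;
}

// predict one row, optionally overriding the value seen for feature `ovar`
// (0-based; -1 = no override) -- used for OOB permutation.
double tree_pred_row(const NumericMatrix& tr, const NumericMatrix& X, int i,
                     int ovar, double oval) {
  int node = 0;
  while (tr(node, 0) != 0.0) {
    const int v = static_cast<int>(tr(node, 0)) - 1;
    const double x = (v == ovar) ? oval : X(i, v);
    node = static_cast<int>((x <= tr(node, 1)) ? tr(node, 2) : tr(node, 3)) - 1;
  }
  return tr(node, 4);
}

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
                     int min_node) {
  const int n = X.nrow(), p = X.ncol();
  // presort every feature once; shared by all trees
  std::vector<int> order(static_cast<std::size_t>(n) * p);
  {
    const double* Xp = X.begin();
    for (int j = 0; j < p; ++j) {
      int* ord = &order[static_cast<std::size_t>(j) * n];
      const double* col = Xp + static_cast<std::size_t>(j) * n;
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord, ord + n,
                [col](int a, int b) { return col[a] < col[b]; });
    }
  }
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  int degenerate = 0;
  std::vector<int> idx;
  idx.reserve(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) inbag(rand_below(n), t)++;
    idx.clear();
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < inbag(i, t); ++c) idx.push_back(i);
    Builder b(X.begin(), y.begin(), n, p, mtry, min_node, order);
    b.build(idx, 0, n);
    if (b.tr.var.size() == 1) ++degenerate;
    trees[t] = pack(b.tr);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["n_single_leaf"] = degenerate);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X,
                                 IntegerVector which_trees) {
  const int n = X.nrow(), nt = which_trees.size();
  NumericVector out(n);
  for (int s = 0; s < nt; ++s) {
    NumericMatrix tr = trees[which_trees[s] - 1];
    for (int i = 0; i < n; ++i) out[i] += tree_pred_row(tr, X, i, -1, 0.0);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// Predictions of one tree on a given row set; `feature` (1-based, 0 = none)
// names a column whose values are shuffled among those rows according to
// `perm`, a permutation of seq_along(rows).
// [[Rcpp::export]]
NumericVector cpp_predict_rows(NumericMatrix tree, NumericMatrix X,
                               IntegerVector rows, int feature,
                               IntegerVector perm) {
  const int B = rows.size();
  NumericVector out(B);
  for (int k = 0; k < B; ++k) {
    const int i = rows[k] - 1;
    if (feature > 0) {
      const double v = X(rows[perm[k] - 1] - 1, feature - 1);
      out[k] = tree_pred_row(tree, X, i, feature - 1, v);
    } else {
      out[k] = tree_pred_row(tree, X, i, -1, 0.0);
    }
  }
  return out;
}

// Per-tree OOB permutation importance:
//   PVIM_t(j) = [ sum_{i in B_t}(y_i - yhat*_ti)^2 - sum_{i in B_t}(y_i - yhat_ti)^2 ] / |B_t|
// oriented so that a feature whose permutation inflates the OOB error gets a
// positive importance; features a tree never splits on contribute exactly 0,
// as does a tree with an empty OOB set.  The reported PVIM is the mean over
// all ntree trees.  One fresh permutation per (tree, feature) pair, drawn
// from R's RNG; features are visited in ascending index order so the stream
// is reproducible.
// [[Rcpp::export]]
List cpp_pvim(List trees, IntegerMatrix inbag, NumericMatrix X, NumericVector y,
              bool keep_per_tree) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericVector pvim(p);
  NumericMatrix PT(keep_per_tree ? ntree : 0, keep_per_tree ? p : 0);
  std::vector<int> oob, perm, used_list;
  std::vector<char> used(p);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int B = static_cast<int>(oob.size());
    if (B == 0) continue;
    double err0 = 0.0;
    for (int k = 0; k < B; ++k) {
      const double r = y[oob[k]] - tree_pred_row(tr, X, oob[k], -1, 0.0);
      err0 += r * r;
    }
    std::fill(used.begin(), used.end(), 0);
    for (int i = 0; i < tr.nrow(); ++i)
      if (tr(i, 0) > 0.0) used[static_cast<int>(tr(i, 0)) - 1] = 1;
    used_list.clear();
    for (int j = 0; j < p; ++j)
      if (used[j]) used_list.push_back(j);
    for (std::size_t m = 0; m < used_list.size(); ++m) {
      const int j = used_list[m];
      perm.resize(B);
      for (int k = 0; k < B; ++k) perm[k] = k;
      for (int k = B - 1; k > 0; --k) std::swap(perm[k], perm[rand_below(k + 1)]);
      double err1 = 0.0;
      for (int k = 0; k < B; ++k) {
        const int i = oob[k];
        const double v = X(oob[perm[k]], j);
        const double r = y[i] - tree_pred_row(tr, X, i, j, v);
        err1 += r * r;
      }
      const double contrib = (err1 - err0) / B;
      pvim[j] += contrib;
      if (keep_per_tree) PT(t, j) = contrib;
    }
  }
  for (int j = 0; j < p; ++j) pvim[j] /= ntree;
  return List::create(_["pvim"] = pvim, _["per_tree"] = PT);
}
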