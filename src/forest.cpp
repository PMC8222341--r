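#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Random forest of gini-impurity CART trees (classification).
//
// Implements the classical ensemble: bootstrap resampling of subjects,
// random feature subsampling at every node (`mtry`), impurity splits with
// depth / leaf-size / split-size limits, per-sample class weights, and mean
// decrease in impurity ("Gini importance") averaged over trees and
// normalized to sum to one.  Written here because no tree learner is
// available in the target environment.

namespace {

struct Node {
  int feature = -1;      // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> dist;  // weighted class distribution (leaves)
};

struct Tree {
  std::vector<Node> nodes;
};

struct BuildCtx {
  const NumericMatrix& X;
  const IntegerVector& y;
  const std::vector<double>& w;  // per-subject weight
  int nclass, mtry, max_depth, min_split, min_leaf;
  std::mt19937& rng;
  std::vector<double>& imp;  // impurity-decrease accumulator (per feature)
  double root_weight = 0.0;
};

double gini_from_counts(const std::vector<double>& cnt, double tot) {
  if (tot <= 0.0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (tot * tot);
}

// Recursively grow a subtree on `idx` (bootstrap indices, duplicates kept).
int grow(Tree& tree, BuildCtx& ctx, std::vector<int>& idx, int depth) {
  const int n = static_cast<int>(idx.size());
  std::vector<double> cnt(ctx.nclass, 0.0);
  double wtot = 0.0;
  for (int i : idx) {
    cnt[ctx.y[i]] += ctx.w[i];
    wtot += ctx.w[i];
  }
  const double imp_node = gini_from_counts(cnt, wtot);

  const int me = static_cast<int>(tree.nodes.size());
  tree.nodes.emplace_back();

  bool make_leaf = (depth >= ctx.max_depth) || (n < ctx.min_split) ||
                   (imp_node <= 0.0) || (n < 2 * ctx.min_leaf);
  int best_f = -1, best_nl = 0;
  double best_thr = 0.0, best_score = -1.0;

  if (!make_leaf) {
    const int p = ctx.X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), ctx.rng);

    std::vector<std::pair<double, int>> vals(n);
    int tried_with_split = 0;
    for (int fi = 0; fi < p; ++fi) {
      if (tried_with_split >= ctx.mtry && best_f >= 0) break;
      const int f = feats[fi];
      for (int k = 0; k < n; ++k) vals[k] = {ctx.X(idx[k], f), idx[k]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      ++tried_with_split;

      std::vector<double> lcnt(ctx.nclass, 0.0);
      double lw = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        const int i = vals[k].second;
        lcnt[ctx.y[i]] += ctx.w[i];
        lw += ctx.w[i];
        if (vals[k].first == vals[k + 1].first) continue;
        const int nl = k + 1, nr = n - nl;
        if (nl < ctx.min_leaf || nr < ctx.min_leaf) continue;
        // maximize sum of squared class weights over child weight
        double sl = 0.0, sr = 0.0;
        for (int c = 0; c < ctx.nclass; ++c) {
          sl += lcnt[c] * lcnt[c];
          const double rc = cnt[c] - lcnt[c];
          sr += rc * rc;
        }
        const double rw = wtot - lw;
        if (lw <= 0.0 || rw <= 0.0) continue;
        const double score = sl / lw + sr / rw;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
          best_nl = nl;
        }
      }
    }
    if (best_f < 0) make_leaf = true;
  }

  if (make_leaf) {
    double s = 0.0;
    for (double c : cnt) s += c;
    for (double& c : cnt) c = (s > 0.0) ? c / s : 1.0 / ctx.nclass;
    tree.nodes[me].dist = cnt;
    return me;
  }

  std::vector<int> lidx, ridx;
  lidx.reserve(best_nl);
  ridx.reserve(n - best_nl);
  std::vector<double> lcnt(ctx.nclass, 0.0);
  double lw = 0.0;
  for (int i : idx) {
    if (ctx.X(i, best_f) <= best_thr) {
      lidx.push_back(i);
      lcnt[ctx.y[i]] += ctx.w[i];
      lw += ctx.w[i];
    } else {
      ridx.push_back(i);
    }
  }
  const double rw = wtot - lw;
  std::vector<double> rcnt(ctx.nclass);
  for (int c = 0; c < ctx.nclass; ++c) rcnt[c] = cnt[c] - lcnt[c];
  const double dec = wtot * imp_node - lw * gini_from_counts(lcnt, lw) -
                     rw * gini_from_counts(rcnt, rw);
  ctx.imp[best_f] += dec / ctx.root_weight;

  idx.clear();
  idx.shrink_to_fit();
  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  tree.nodes[me].left = grow(tree, ctx, lidx, depth + 1);
  tree.nodes[me].right = grow(tree, ctx, ridx, depth + 1);
  return me;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int max_depth, int min_split, int min_leaf,
                NumericVector class_weight, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) w[i] = class_weight[y[i]];

  NumericVector importance(p);
  List trees(ntree);
  std::vector<double> imp_tree(p);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::fill(imp_tree.begin(), imp_tree.end(), 0.0);
    Tree tree;
    BuildCtx ctx{X,        y,         w,        nclass, mtry,
                 max_depth, min_split, min_leaf, rng,    imp_tree};
    for (int i : idx) ctx.root_weight += w[i];
    grow(tree, ctx, idx, 0);

    const int m = static_cast<int>(tree.nodes.size());
    IntegerVector feat(m), left(m), right(m);
    NumericVector thr(m);
    NumericMatrix dist(m, nclass);
    for (int k = 0; k < m; ++k) {
      feat[k] = tree.nodes[k].feature;
      thr[k] = tree.nodes[k].threshold;
      left[k] = tree.nodes[k].left;
      right[k] = tree.nodes[k].right;
      if (feat[k] < 0)
        for (int c = 0; c < nclass; ++c) dist(k, c) = tree.nodes[k].dist[c];
    }
    trees[t] = List::create(_["feature"] = feat, _["threshold"] = thr,
                            _["left"] = left, _["right"] = right,
                            _["dist"] = dist);
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += imp_tree[j];
    if (s > 0.0)
      for (int j = 0; j < p; ++j) importance[j] += imp_tree[j] / s;
  }
  double s = 0.0;
  for (int j = 0; j < p; ++j) s += importance[j];
  if (s > 0.0)
    for (int j = 0; j < p; ++j) importance[j] /= s;

  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["nclass"] = nclass, _["p"] = p);
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int nclass = as<int>(forest["nclass"]);
  const int n = X.nrow(), ntree = trees.size();
  NumericMatrix prob(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"];
    NumericMatrix dist = tr["dist"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feat[k] >= 0) k = (X(i, feat[k]) <= thr[k]) ? left[k] : right[k];
      for (int c = 0; c < nclass; ++c) prob(i, c) += dist(k, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) prob(i, c) /= ntree;
  return prob;
}
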