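#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Tree stored as parallel arrays; feature == -1 marks a terminal node.
struct Tree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> p_a;
  std::vector<double> p_b;
};

// Probability that a sample with observed feature value x crosses to the
// right of `thr` when the feature carries Gaussian uncertainty sd_x.
// sd_x == 0 gives deterministic routing (0 left, 1 right for binary bits).
static inline double route_right(double x, double sd_x, double thr) {
  if (sd_x <= 0.0) return (x > thr) ? 1.0 : 0.0;
  return R::pnorm(x - thr, 0.0, sd_x, 1, 0);
}

class Grower {
public:
  const NumericMatrix& x;
  const NumericVector& py;   // per-sample probability of class A (active)
  const NumericVector& dx;   // per-feature Gaussian sd (0 = no uncertainty)
  int mtry, max_depth, min_split;
  double keep_proba;
  Tree tree;

  Grower(const NumericMatrix& x_, const NumericVector& py_,
         const NumericVector& dx_, int mtry_, int max_depth_, int min_split_,
         double keep_proba_)
    : x(x_), py(py_), dx(dx_), mtry(mtry_), max_depth(max_depth_),
      min_split(min_split_), keep_proba(keep_proba_) {}

  int grow(std::vector<int>& idx, std::vector<double>& pi, int depth) {
    const int n = (int)idx.size();
    double s = 0.0, s_a = 0.0;
    for (int k = 0; k < n; ++k) {
      s += pi[k];
      s_a += pi[k] * py[idx[k]];
    }
    const double pa = s_a / s;
    const double pb = 1.0 - pa;
    const double gini = 1.0 - (pa * pa + pb * pb);

    const bool stop = (depth >= max_depth) || (n < min_split) ||
                      (gini < 1e-12);

    int best_f = -1;
    double best_cost = gini;  // a split must strictly beat the node impurity
    if (!stop) {
      IntegerVector cand = sample(x.ncol(), mtry, false);  // R RNG, 1-based
      std::sort(cand.begin(), cand.end());                 // ties -> lowest id
      for (int c = 0; c < cand.size(); ++c) {
        const int f = cand[c] - 1;
        double sl = 0.0, sr = 0.0, sal = 0.0, sar = 0.0;
        for (int k = 0; k < n; ++k) {
          const double pr = route_right(x(idx[k], f), dx[f], 0.5);
          const double mr = pi[k] * pr;
          const double ml = pi[k] - mr;
          sl += ml; sr += mr;
          sal += ml * py[idx[k]];
          sar += mr * py[idx[k]];
        }
        if (sl <= 0.0 || sr <= 0.0) continue;  // one-sided: rejected
        const double pal = sal / sl, par = sar / sr;
        const double gl = 1.0 - (pal * pal + (1.0 - pal) * (1.0 - pal));
        const double gr = 1.0 - (par * par + (1.0 - par) * (1.0 - par));
        const double cost = (sl * gl + sr * gr) / (sl + sr);
        if (cost < best_cost) {
          best_cost = cost;
          best_f = f;
        }
      }
    }

    const int me = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.5);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.p_a.push_back(pa);
    tree.p_b.push_back(pb);

    if (best_f >= 0) {
      std::vector<int> idx_l, idx_r;
      std::vector<double> pi_l, pi_r;
      const double floor_mass = (keep_proba > 0.0) ? keep_proba : 0.0;
      for (int k = 0; k < n; ++k) {
        const double pr = route_right(x(idx[k], best_f), dx[best_f], 0.5);
        const double mr = pi[k] * pr;
        const double ml = pi[k] - mr;
        if (ml > 0.0 && ml >= floor_mass) { idx_l.push_back(idx[k]); pi_l.push_back(ml); }
        if (mr > 0.0 && mr >= floor_mass) { idx_r.push_back(idx[k]); pi_r.push_back(mr); }
      }
      if (!idx_l.empty() && !idx_r.empty()) {
        tree.feature[me] = best_f;
        const int l = grow(idx_l, pi_l, depth + 1);
        const int r = grow(idx_r, pi_r, depth + 1);
        tree.left[me] = l;
        tree.right[me] = r;
      }
    }
    return me;
  }
};

static List tree_to_list(const Tree& t) {
  return List::create(
    _["feature"] = wrap(t.feature),
    _["threshold"] = wrap(t.threshold),
    _["left"] = wrap(t.left),
    _["right"] = wrap(t.right),
    _["p_a"] = wrap(t.p_a),
    _["p_b"] = wrap(t.p_b));
}

// [[Rcpp::export(name = ".grow_forest")]]
List grow_forest(NumericMatrix x, NumericVector py, NumericVector dx,
                 int n_trees, int mtry, int max_depth, int min_split,
                 double keep_proba, bool bootstrap) {
  const int n = x.nrow();
  List out(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      IntegerVector bs = sample(n, n, true);  // R RNG, 1-based
      for (int i = 0; i < n; ++i) idx[i] = bs[i] - 1;
      std::sort(idx.begin(), idx.end());      // canonical order for summation
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<double> pi(n, 1.0);
    Grower g(x, py, dx, mtry, max_depth, min_split, keep_proba);
    g.grow(idx, pi, 0);
    out[t] = tree_to_list(g.tree);
  }
  return out;
}

// Propagate one sample through one tree: branches whose probability mass
// falls below keep_proba are pruned; if both children fall below, the
// higher-mass child survives (never an empty prediction); the surviving
// mass is renormalised so Pr_A + Pr_B == 1.
static double predict_tree(const IntegerVector& feature,
                           const NumericVector& threshold,
                           const IntegerVector& left,
                           const IntegerVector& right,
                           const NumericVector& p_a,
                           const NumericMatrix& x, int i,
                           const NumericVector& dx, double keep_proba) {
  double mass = 0.0, mass_a = 0.0;
  std::vector<std::pair<int, double> > stack;
  stack.push_back(std::make_pair(0, 1.0));
  while (!stack.empty()) {
    const int node = stack.back().first;
    const double pi = stack.back().second;
    stack.pop_back();
    const int f = feature[node];
    if (f < 0) {
      mass += pi;
      mass_a += pi * p_a[node];
      continue;
    }
    const double pr = route_right(x(i, f), dx[f], threshold[node]);
    const double mr = pi * pr;
    const double ml = pi - mr;
    const bool keep_l = ml > 0.0 && ml >= keep_proba;
    const bool keep_r = mr > 0.0 && mr >= keep_proba;
    if (keep_l) stack.push_back(std::make_pair(left[node], ml));
    if (keep_r) stack.push_back(std::make_pair(right[node], mr));
    if (!keep_l && !keep_r) {
      // fall back to the highest-mass branch (ties go left)
      if (ml >= mr) stack.push_back(std::make_pair(left[node], ml));
      else stack.push_back(std::make_pair(right[node], mr));
    }
  }
  return mass_a / mass;
}

// [[Rcpp::export(name = ".predict_forest")]]
NumericMatrix predict_forest(List trees, NumericMatrix x, NumericVector dx,
                             double keep_proba) {
  const int n = x.nrow();
  const int nt = trees.size();
  NumericMatrix out(n, nt);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector p_a = tr["p_a"];
    for (int i = 0; i < n; ++i)
      out(i, t) = predict_tree(feature, threshold, left, right, p_a,
                               x, i, dx, keep_proba);
  }
  return out;
}
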