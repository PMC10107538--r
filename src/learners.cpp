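// Depth-limited decision-tree ensembles and the nested leave-one-out
// cross-validation loop.  One split engine serves both learners: for the
// random forest the response is the 0/1 label with bootstrap-count weights
// (Gini splitting on a binary label equals weighted variance splitting);
// for gradient boosting the response is the logistic-loss gradient
// residual with unit weights and Newton leaf values.
//
// Split search uses quantile-binned histograms (16 bins, fit on each outer
// training fold), the standard discretisation of modern boosting
// libraries; candidate thresholds are midpoints of the raw feature values
// flanking each bin edge, so fitted trees predict on raw values.
//
// All randomness (fold shuffles, bootstrap draws, feature subsampling)
// comes from R's RNG so that set.seed() in R reproduces runs exactly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <numeric>
#include <vector>
using namespace Rcpp;

static const int N_BINS = 16;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct Binned {
  int m = 0, p = 0;
  std::vector<uint8_t> code;               // m*p, column-major bin index
  std::vector<std::vector<double>> thr;    // per feature, ascending cuts
};

// quantile binning; features with few distinct values get exact cuts
static Binned make_binned(const std::vector<double>& X, int m, int p) {
  Binned bx;
  bx.m = m; bx.p = p;
  bx.code.assign((size_t)m * p, 0);
  bx.thr.resize(p);
  std::vector<double> v(m);
  for (int j = 0; j < p; j++) {
    const double* xj = &X[(size_t)j * m];
    std::copy(xj, xj + m, v.begin());
    std::sort(v.begin(), v.end());
    std::vector<double> distinct;
    for (int i = 0; i < m; i++)
      if (distinct.empty() || v[i] > distinct.back()) distinct.push_back(v[i]);
    std::vector<double>& t = bx.thr[j];
    if ((int)distinct.size() <= N_BINS) {
      for (size_t k = 1; k < distinct.size(); k++)
        t.push_back(0.5 * (distinct[k - 1] + distinct[k]));
    } else {
      for (int b = 1; b < N_BINS; b++) {
        int hi = (int)((long long)b * m / N_BINS);
        if (hi <= 0 || hi >= m) continue;
        if (v[hi] > v[hi - 1]) t.push_back(0.5 * (v[hi - 1] + v[hi]));
      }
    }
    uint8_t* cj = &bx.code[(size_t)j * m];
    for (int i = 0; i < m; i++)
      cj[i] = (uint8_t)(std::upper_bound(t.begin(), t.end(), xj[i]) -
                        t.begin());
  }
  return bx;
}

struct Node {
  int feat = -1;          // -1: leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double val = 0.0;       // leaf prediction
  double W = 0.0, S = 0.0; // sum of weights / weighted response
};

// Level-wise histogram-split regression tree.  Samples with w[i] <= 0 are
// excluded.  mtry < p activates per-node feature subsampling.  node_of
// (size m) receives final leaf ids.
static std::vector<Node> build_tree(const Binned& bx,
                                    const std::vector<double>& resp,
                                    const std::vector<double>& w,
                                    int max_depth, int mtry,
                                    std::vector<int>& node_of) {
  int m = bx.m, p = bx.p;
  std::vector<Node> tree;
  tree.reserve(2 << max_depth);
  Node root;
  for (int i = 0; i < m; i++) {
    if (w[i] > 0) {
      root.W += w[i];
      root.S += w[i] * resp[i];
      node_of[i] = 0;
    } else node_of[i] = -1;
  }
  tree.push_back(root);
  std::vector<int> active{0};
  std::vector<int> fscratch(p);
  std::vector<double> hw((size_t)(1 << max_depth) * N_BINS);
  std::vector<double> hs((size_t)(1 << max_depth) * N_BINS);

  for (int d = 0; d < max_depth && !active.empty(); d++) {
    int nn = (int)tree.size(), A = (int)active.size();
    std::vector<double> bg(nn), bthr(nn, 0.0);
    std::vector<int> bfeat(nn, -1), slot(nn, -1);
    for (int a = 0; a < A; a++) {
      int nd = active[a];
      slot[nd] = a;
      bg[nd] = tree[nd].S * tree[nd].S / tree[nd].W + 1e-9;
    }

    std::vector<char> use;
    if (mtry < p) {
      use.assign((size_t)A * p, 0);
      for (int a = 0; a < A; a++) {
        std::iota(fscratch.begin(), fscratch.end(), 0);
        for (int k = 0; k < mtry; k++) {
          int r = k + (int)(unif_rand() * (p - k));
          if (r >= p) r = p - 1;
          std::swap(fscratch[k], fscratch[r]);
          use[(size_t)a * p + fscratch[k]] = 1;
        }
      }
    }

    for (int j = 0; j < p; j++) {
      int nb = (int)bx.thr[j].size();
      if (nb == 0) continue;
      std::fill(hw.begin(), hw.begin() + (size_t)A * N_BINS, 0.0);
      std::fill(hs.begin(), hs.begin() + (size_t)A * N_BINS, 0.0);
      const uint8_t* cj = &bx.code[(size_t)j * m];
      for (int i = 0; i < m; i++) {
        int nd = node_of[i];
        if (nd < 0) continue;
        int sl = slot[nd];
        if (sl < 0) continue;
        if (!use.empty() && !use[(size_t)sl * p + j]) continue;
        size_t h = (size_t)sl * N_BINS + cj[i];
        hw[h] += w[i];
        hs[h] += w[i] * resp[i];
      }
      for (int a = 0; a < A; a++) {
        int nd = active[a];
        double wl = 0, sl_ = 0;
        const double W = tree[nd].W, S = tree[nd].S;
        for (int b = 0; b < nb; b++) {
          double hwb = hw[(size_t)a * N_BINS + b];
          if (hwb <= 0) continue;        // same partition as previous cut
          wl += hwb;
          sl_ += hs[(size_t)a * N_BINS + b];
          double wr = W - wl;
          if (wr <= 0) break;
          double gain = sl_ * sl_ / wl + (S - sl_) * (S - sl_) / wr;
          if (gain > bg[nd]) {
            bg[nd] = gain; bfeat[nd] = j; bthr[nd] = bx.thr[j][b];
          }
        }
      }
    }

    std::vector<int> next;
    std::vector<int> cutidx(nn, -1);   // route by bin index: code < cut
    for (int a : active) {
      if (bfeat[a] >= 0) {
        tree[a].feat = bfeat[a];
        tree[a].thr = bthr[a];
        const std::vector<double>& tj = bx.thr[bfeat[a]];
        cutidx[a] = (int)(std::upper_bound(tj.begin(), tj.end(), bthr[a]) -
                          tj.begin());
        tree[a].left = (int)tree.size(); tree.push_back(Node());
        tree[a].right = (int)tree.size(); tree.push_back(Node());
        next.push_back(tree[a].left);
        next.push_back(tree[a].right);
      }
    }
    if (next.empty()) break;
    for (int i = 0; i < m; i++) {
      int nd = node_of[i];
      if (nd < 0 || nd >= nn || cutidx[nd] < 0) continue;
      bool goleft = bx.code[(size_t)tree[nd].feat * m + i] < cutidx[nd];
      int c = goleft ? tree[nd].left : tree[nd].right;
      node_of[i] = c;
      tree[c].W += w[i];
      tree[c].S += w[i] * resp[i];
    }
    active.swap(next);
  }
  return tree;
}

static inline double tree_predict(const std::vector<Node>& tr,
                                  const double* x) {
  int nd = 0;
  while (tr[nd].feat >= 0)
    nd = (x[tr[nd].feat] <= tr[nd].thr) ? tr[nd].left : tr[nd].right;
  return tr[nd].val;
}

struct Ensemble {
  double F0 = 0.0;     // gb only
  bool gb = false;
  std::vector<std::vector<Node>> trees;
  double predict(const double* x) const {
    if (gb) {
      double F = F0;
      for (const auto& t : trees) F += tree_predict(t, x);
      return sigmoid(F);
    }
    double s = 0.0;
    for (const auto& t : trees) s += tree_predict(t, x);
    return trees.empty() ? 0.5 : s / trees.size();
  }
};

// gradient boosting with logistic loss, Friedman residual trees, Newton
// leaf values (clipped), shrinkage lr
static Ensemble gb_fit(const Binned& bx, const std::vector<int>& y,
                       const std::vector<char>& in_mask,
                       int n_trees, double lr, int depth) {
  int m = bx.m, p = bx.p;
  Ensemble mod; mod.gb = true;
  double sy = 0, sw = 0;
  for (int i = 0; i < m; i++) if (in_mask[i]) { sy += y[i]; sw += 1; }
  double pbar = std::min(std::max(sy / sw, 1e-6), 1.0 - 1e-6);
  mod.F0 = std::log(pbar / (1.0 - pbar));
  std::vector<double> F(m, mod.F0), resp(m, 0.0), w(m, 0.0);
  for (int i = 0; i < m; i++) if (in_mask[i]) w[i] = 1.0;
  std::vector<int> node_of(m);
  for (int t = 0; t < n_trees; t++) {
    for (int i = 0; i < m; i++)
      if (in_mask[i]) resp[i] = y[i] - sigmoid(F[i]);
    std::vector<Node> tree = build_tree(bx, resp, w, depth, p, node_of);
    int nl = (int)tree.size();
    std::vector<double> sr(nl, 0.0), sh(nl, 0.0);
    for (int i = 0; i < m; i++) {
      if (!in_mask[i]) continue;
      double pi = sigmoid(F[i]);
      sr[node_of[i]] += y[i] - pi;
      sh[node_of[i]] += pi * (1.0 - pi);
    }
    for (int k = 0; k < nl; k++) {
      if (tree[k].feat >= 0) continue;
      double v = sr[k] / (sh[k] + 1e-12);
      tree[k].val = lr * std::min(std::max(v, -4.0), 4.0);
    }
    for (int i = 0; i < m; i++)
      if (in_mask[i]) F[i] += tree[node_of[i]].val;
    mod.trees.push_back(std::move(tree));
  }
  return mod;
}

// random forest: bootstrap of the in-mask subset, per-node mtry = sqrt(p),
// Gini splits, leaf value = weighted class fraction, averaged over trees
static Ensemble rf_fit(const Binned& bx, const std::vector<int>& y,
                       const std::vector<char>& in_mask,
                       int n_trees, int depth) {
  int m = bx.m, p = bx.p;
  Ensemble mod;
  std::vector<int> subset;
  for (int i = 0; i < m; i++) if (in_mask[i]) subset.push_back(i);
  int ms = (int)subset.size();
  int mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  std::vector<double> resp(m, 0.0), w(m);
  for (int i : subset) resp[i] = y[i];
  std::vector<int> node_of(m);
  for (int t = 0; t < n_trees; t++) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int k = 0; k < ms; k++) {
      int r = (int)(unif_rand() * ms);
      if (r >= ms) r = ms - 1;
      w[subset[r]] += 1.0;
    }
    std::vector<Node> tree = build_tree(bx, resp, w, depth, mtry, node_of);
    for (auto& nd : tree)
      if (nd.feat < 0) nd.val = (nd.W > 0) ? nd.S / nd.W : 0.5;
    mod.trees.push_back(std::move(tree));
  }
  return mod;
}

static Ensemble fit_ensemble(const Binned& bx, const std::vector<int>& y,
                             const std::vector<char>& in_mask, bool rf,
                             int n_trees, double lr, int depth) {
  return rf ? rf_fit(bx, y, in_mask, n_trees, depth)
            : gb_fit(bx, y, in_mask, n_trees, lr, depth);
}

static double mcc_at_half(const std::vector<double>& prob,
                          const std::vector<int>& y) {
  double tp = 0, fp = 0, fn = 0, tn = 0;
  for (size_t i = 0; i < y.size(); i++) {
    bool ph = prob[i] > 0.5;
    if (y[i] == 1) { if (ph) tp++; else fn++; }
    else           { if (ph) fp++; else tn++; }
  }
  double den = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (den <= 0) return 0.0;
  return (tp * tn - fp * fn) / std::sqrt(den);
}

static void shuffle_rng(std::vector<int>& v) {
  for (int k = (int)v.size() - 1; k > 0; k--) {
    int r = (int)(unif_rand() * (k + 1));
    if (r > k) r = k;
    std::swap(v[k], v[r]);
  }
}

// stratified fold labels 0..n_folds-1
static std::vector<int> stratified_folds(const std::vector<int>& y, int m,
                                         int n_folds) {
  std::vector<int> pos, neg, fold(m, -1);
  for (int i = 0; i < m; i++) (y[i] == 1 ? pos : neg).push_back(i);
  shuffle_rng(pos);
  shuffle_rng(neg);
  for (size_t k = 0; k < pos.size(); k++) fold[pos[k]] = (int)(k % n_folds);
  for (size_t k = 0; k < neg.size(); k++) fold[neg[k]] = (int)(k % n_folds);
  return fold;
}

// [[Rcpp::export]]
List cpp_nested_loocv(NumericMatrix X, IntegerVector y, bool random_forest,
                      int n_trees, double learning_rate,
                      IntegerVector depth_grid, int n_folds, int n_rep,
                      Nullable<NumericMatrix> newdata = R_NilValue) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix XN = newdata.isNotNull() ? NumericMatrix(newdata) : X;
  if (XN.nrow() != n || XN.ncol() != p)
    stop("newdata must match the dimensions of X");
  NumericVector prob(n);
  IntegerVector chosen(n);
  int ng = depth_grid.size();
  std::vector<int> grid(depth_grid.begin(), depth_grid.end());

  std::vector<double> Xtr;
  std::vector<int> map(n - 1);

  for (int i_out = 0; i_out < n; i_out++) {
    int m = 0;
    for (int i = 0; i < n; i++) if (i != i_out) map[m++] = i;
    std::vector<int> ytr(m);
    for (int k = 0; k < m; k++) ytr[k] = y[map[k]];

    // impute with training-fold column means (no leakage from the held-out
    // subject); the held-out row comes from `newdata` when supplied
    Xtr.assign((size_t)m * p, 0.0);
    std::vector<double> xte(p);
    for (int j = 0; j < p; j++) {
      double s = 0; int c = 0;
      for (int k = 0; k < m; k++) {
        double v = X(map[k], j);
        if (!ISNAN(v)) { s += v; c++; }
      }
      double mu = c ? s / c : 0.0;
      for (int k = 0; k < m; k++) {
        double v = X(map[k], j);
        Xtr[(size_t)j * m + k] = ISNAN(v) ? mu : v;
      }
      double vt = XN(i_out, j);
      xte[j] = ISNAN(vt) ? mu : vt;
    }

    int npos = 0;
    for (int k = 0; k < m; k++) npos += ytr[k];
    if (npos < 2 || m - npos < 2)
      stop("each training set needs at least two subjects per class");

    Binned bx = make_binned(Xtr, m, p);

    std::vector<double> score(ng, 0.0), preds(m, 0.0);
    std::vector<char> in_mask(m);
    std::vector<double> xrow(p);
    for (int rep = 0; rep < n_rep; rep++) {
      std::vector<int> fold = stratified_folds(ytr, m, n_folds);
      for (int g = 0; g < ng; g++) {
        for (int f = 0; f < n_folds; f++) {
          for (int k = 0; k < m; k++) in_mask[k] = (fold[k] != f);
          Ensemble mod = fit_ensemble(bx, ytr, in_mask, random_forest,
                                      n_trees, learning_rate, grid[g]);
          for (int k = 0; k < m; k++) {
            if (fold[k] != f) continue;
            for (int j = 0; j < p; j++) xrow[j] = Xtr[(size_t)j * m + k];
            preds[k] = mod.predict(&xrow[0]);
          }
        }
        score[g] += mcc_at_half(preds, ytr) / n_rep;
      }
    }

    // depth maximising mean inner MCC, ties broken toward shallower trees
    int best = 0;
    for (int g = 1; g < ng; g++) {
      bool better = score[g] > score[best] + 1e-12 ||
                    (score[g] > score[best] - 1e-12 && grid[g] < grid[best]);
      if (better) best = g;
    }

    std::fill(in_mask.begin(), in_mask.end(), 1);
    Ensemble full = fit_ensemble(bx, ytr, in_mask, random_forest,
                                 n_trees, learning_rate, grid[best]);
    prob[i_out] = full.predict(&xte[0]);
    chosen[i_out] = grid[best];
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["probability"] = prob, _["chosen_depth"] = chosen);
}

// single fit + predict (used by unit tests and the CLI's refit mode)
// [[Rcpp::export]]
NumericVector cpp_fit_predict(NumericMatrix Xtr, IntegerVector ytr,
                              NumericMatrix Xte, bool random_forest,
                              int n_trees, double learning_rate, int depth) {
  int m = Xtr.nrow(), p = Xtr.ncol();
  std::vector<double> X((size_t)m * p), mu(p, 0.0);
  for (int j = 0; j < p; j++) {
    double s = 0; int c = 0;
    for (int k = 0; k < m; k++) {
      double v = Xtr(k, j);
      if (!ISNAN(v)) { s += v; c++; }
    }
    mu[j] = c ? s / c : 0.0;
    for (int k = 0; k < m; k++) {
      double v = Xtr(k, j);
      X[(size_t)j * m + k] = ISNAN(v) ? mu[j] : v;
    }
  }
  std::vector<int> y(ytr.begin(), ytr.end());
  std::vector<char> in_mask(m, 1);
  Binned bx = make_binned(X, m, p);
  Ensemble mod = fit_ensemble(bx, y, in_mask, random_forest, n_trees,
                              learning_rate, depth);
  NumericVector out(Xte.nrow());
  std::vector<double> xrow(p);
  for (int k = 0; k < Xte.nrow(); k++) {
    for (int j = 0; j < p; j++) {
      double v = Xte(k, j);
      xrow[j] = ISNAN(v) ? mu[j] : v;
    }
    out[k] = mod.predict(&xrow[0]);
  }
  return out;
}
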