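#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Deterministic splitmix64 generator so forests are reproducible across
// platforms and independent of R's RNG state.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Params {
  int num_trees;
  int mtry;
  double sample_fraction;
  double honesty_fraction;
  double alpha;
  int min_node_size;
  uint64_t seed;
};

// Growing tree state (arrays indexed by node id).
struct TreeBuf {
  std::vector<int> var;      // split covariate (0-based), -1 for leaf
  std::vector<double> thr;   // split threshold (x <= thr goes left)
  std::vector<int> left, right, depth;
  std::vector<double> gain;  // split criterion improvement (0 for leaves)
  std::vector<int> n_struct, n_est;
  std::vector<double> tau;   // node-level effect estimate (IV trees)
  // per-leaf estimation-half moment statistics:
  // regression: col0 = mean(t); iv: means of (y, d, z, y*z, d*z)
  std::vector<std::array<double, 5> > stats;

  int new_node(int d) {
    var.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1); depth.push_back(d);
    gain.push_back(0.0); n_struct.push_back(0); n_est.push_back(0);
    tau.push_back(NA_REAL);
    stats.push_back({NA_REAL, NA_REAL, NA_REAL, NA_REAL, NA_REAL});
    return (int)var.size() - 1;
  }
};

// Best split of a node by the partitioned-sum criterion
// sum_children (sum rho)^2 / n_child, evaluated on the structure half.
// Candidate thresholds are midpoints between consecutive distinct observed
// values; ties in the criterion resolve to the lowest covariate index then
// the lowest threshold (covariates scanned in ascending index order).
static bool find_best_split(const NumericMatrix &X,
                            const std::vector<int> &su,
                            const std::vector<int> &eu,
                            const std::vector<double> &rho,
                            const Params &par, Rng &rng,
                            int &best_var, double &best_thr, double &best_gain) {
  const int p = X.ncol();
  const int n = (int)su.size();
  int min_child = std::max(par.min_node_size,
                           (int)std::ceil(par.alpha * (double)n));
  if (n < 2 * min_child) return false;

  double S = 0.0;
  for (int i = 0; i < n; ++i) S += rho[i];
  const double parent_crit = S * S / (double)n;

  // sample mtry covariates without replacement, then scan in ascending order
  int m = std::min(par.mtry, p);
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  for (int j = 0; j < m; ++j) {
    int k = j + rng.below(p - j);
    std::swap(cand[j], cand[k]);
  }
  cand.resize(m);
  std::sort(cand.begin(), cand.end());

  best_var = -1; best_thr = 0.0; best_gain = 0.0;
  const double eps = 1e-12 * (1.0 + std::fabs(parent_crit));

  std::vector<std::pair<double, double> > xv(n); // (x, rho)
  std::vector<double> ev;
  ev.reserve(eu.size());

  for (size_t c = 0; c < cand.size(); ++c) {
    int j = cand[c];
    for (int i = 0; i < n; ++i) xv[i] = std::make_pair(X(su[i], j), rho[i]);
    std::sort(xv.begin(), xv.end());
    if (xv.front().first == xv.back().first) continue; // constant in node

    ev.clear();
    for (size_t i = 0; i < eu.size(); ++i) ev.push_back(X(eu[i], j));
    std::sort(ev.begin(), ev.end());

    double SL = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      SL += xv[i].second;
      if (xv[i].first == xv[i + 1].first) continue;
      int nL = i + 1, nR = n - nL;
      if (nL < min_child || nR < min_child) continue;
      double th = 0.5 * (xv[i].first + xv[i + 1].first);
      // each child must receive at least one estimation-half unit
      size_t eL = std::upper_bound(ev.begin(), ev.end(), th) - ev.begin();
      if (eL < 1 || eL > ev.size() - 1) continue;
      double SR = S - SL;
      double crit = SL * SL / (double)nL + SR * SR / (double)nR;
      double g = crit - parent_crit;
      if (g > best_gain + eps || (best_var < 0 && g > eps)) {
        if (g > best_gain) { best_gain = g; best_var = j; best_thr = th; }
      }
    }
  }
  return best_var >= 0;
}

static inline double node_mean(const std::vector<double> &v) {
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += v[i];
  return v.empty() ? NA_REAL : s / (double)v.size();
}

// Recursive growth. type 0: regression on R(,0). type 1: instrumental,
// R columns (ytil, dtil, ztil); splitting uses the gradient pseudo-outcome
// rho_i = ztil_i * (ytil_i - tau_p * dtil_i) / A_p with A_p = mean(ztil*dtil).
static void grow_node(const NumericMatrix &X, const NumericMatrix &R, int type,
                      const Params &par, Rng &rng, TreeBuf &tb, int node,
                      std::vector<int> &su, std::vector<int> &eu,
                      double parent_tau, bool is_root) {
  const int n = (int)su.size();
  tb.n_struct[node] = n;
  tb.n_est[node] = (int)eu.size();

  double tau_p = parent_tau, A = NA_REAL;
  std::vector<double> rho(n);
  if (type == 0) {
    for (int i = 0; i < n; ++i) rho[i] = R(su[i], 0);
  } else {
    double sy = 0, sd = 0, sz = 0, syz = 0, sdz = 0;
    for (int i = 0; i < n; ++i) {
      double y = R(su[i], 0), d = R(su[i], 1), z = R(su[i], 2);
      sy += y; sd += d; sz += z; syz += y * z; sdz += d * z;
    }
    double cyz = syz / n - (sy / n) * (sz / n);
    double cdz = sdz / n - (sd / n) * (sz / n);
    A = sdz / n;
    if (std::fabs(cdz) > 1e-10) tau_p = cyz / cdz;
    tb.tau[node] = tau_p;
    if (std::fabs(A) < 1e-10) {
      if (is_root) stop("weak instrument: root moment mean(Ztil*Dtil) is degenerate");
      // leaf: fall through without splitting
    } else {
      for (int i = 0; i < n; ++i)
        rho[i] = R(su[i], 2) * (R(su[i], 0) - tau_p * R(su[i], 1)) / A;
    }
  }

  int bv; double bt, bg;
  bool can_split = (type == 1 && std::fabs(A) < 1e-10)
                       ? false
                       : find_best_split(X, su, eu, rho, par, rng, bv, bt, bg);

  if (!can_split) {
    // leaf: estimation-half statistics (honesty: structure responses unused)
    const int ne = (int)eu.size();
    if (type == 0) {
      std::vector<double> t(ne);
      for (int i = 0; i < ne; ++i) t[i] = R(eu[i], 0);
      tb.stats[node][0] = node_mean(t);
    } else {
      double sy = 0, sd = 0, sz = 0, syz = 0, sdz = 0;
      for (int i = 0; i < ne; ++i) {
        double y = R(eu[i], 0), d = R(eu[i], 1), z = R(eu[i], 2);
        sy += y; sd += d; sz += z; syz += y * z; sdz += d * z;
      }
      if (ne > 0) {
        tb.stats[node][0] = sy / ne; tb.stats[node][1] = sd / ne;
        tb.stats[node][2] = sz / ne; tb.stats[node][3] = syz / ne;
        tb.stats[node][4] = sdz / ne;
        double cyz = syz / ne - (sy / ne) * (sz / ne);
        double cdz = sdz / ne - (sd / ne) * (sz / ne);
        tb.tau[node] = (std::fabs(cdz) > 1e-10) ? cyz / cdz : tau_p;
      }
    }
    return;
  }

  tb.var[node] = bv; tb.thr[node] = bt; tb.gain[node] = bg;
  std::vector<int> suL, suR, euL, euR;
  for (int i = 0; i < n; ++i)
    (X(su[i], bv) <= bt ? suL : suR).push_back(su[i]);
  for (size_t i = 0; i < eu.size(); ++i)
    (X(eu[i], bv) <= bt ? euL : euR).push_back(eu[i]);

  int nl = tb.new_node(tb.depth[node] + 1);
  int nr = tb.new_node(tb.depth[node] + 1);
  tb.left[node] = nl; tb.right[node] = nr;
  grow_node(X, R, type, par, rng, tb, nl, suL, euL, tau_p, false);
  grow_node(X, R, type, par, rng, tb, nr, suR, euR, tau_p, false);
}

static Params read_params(const List &params) {
  Params p;
  p.num_trees = as<int>(params["num_trees"]);
  p.mtry = as<int>(params["mtry"]);
  p.sample_fraction = as<double>(params["sample_fraction"]);
  p.honesty_fraction = as<double>(params["honesty_fraction"]);
  p.alpha = as<double>(params["alpha"]);
  p.min_node_size = as<int>(params["min_node_size"]);
  p.seed = (uint64_t)as<double>(params["seed"]);
  return p;
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericMatrix R, int type, List params) {
  Params par = read_params(params);
  const int n = X.nrow();
  int s = std::max(2, (int)std::floor(par.sample_fraction * n));
  if (s > n) s = n;
  int ns = (int)std::round(par.honesty_fraction * s);
  ns = std::max(1, std::min(s - 1, ns));

  List trees(par.num_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < par.num_trees; ++t) {
    Rng rng(par.seed * 0x100000001b3ULL + (uint64_t)(t + 1) * 0x9E3779B9ULL);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < s; ++i) {
      int k = i + rng.below(n - i);
      std::swap(idx[i], idx[k]);
    }
    std::vector<int> su(idx.begin(), idx.begin() + ns);
    std::vector<int> eu(idx.begin() + ns, idx.begin() + s);

    TreeBuf tb;
    int root = tb.new_node(1);
    grow_node(X, R, type, par, rng, tb, root, su, eu, NA_REAL, true);

    int nn = (int)tb.var.size();
    IntegerVector var(nn), left(nn), right(nn), depth(nn), nstr(nn), nest(nn);
    NumericVector thr(nn), gain(nn), tau(nn);
    NumericMatrix stats(nn, 5);
    for (int i = 0; i < nn; ++i) {
      var[i] = tb.var[i] < 0 ? NA_INTEGER : tb.var[i] + 1; // 1-based for R
      left[i] = tb.left[i] < 0 ? NA_INTEGER : tb.left[i] + 1;
      right[i] = tb.right[i] < 0 ? NA_INTEGER : tb.right[i] + 1;
      depth[i] = tb.depth[i];
      nstr[i] = tb.n_struct[i]; nest[i] = tb.n_est[i];
      thr[i] = tb.thr[i]; gain[i] = tb.gain[i]; tau[i] = tb.tau[i];
      for (int k = 0; k < 5; ++k) stats(i, k) = tb.stats[i][k];
    }
    IntegerVector sub(s), est(s - ns);
    for (int i = 0; i < s; ++i) sub[i] = idx[i] + 1;
    for (int i = ns; i < s; ++i) est[i - ns] = idx[i] + 1;

    trees[t] = List::create(
        _["var"] = var, _["threshold"] = thr, _["left"] = left,
        _["right"] = right, _["depth"] = depth, _["gain"] = gain,
        _["tau"] = tau, _["n_struct"] = nstr, _["n_est"] = nest,
        _["stats"] = stats, _["subsample"] = sub, _["est_units"] = est);
  }
  return trees;
}

struct TreeView {
  IntegerVector var, left, right;
  NumericVector thr;
  explicit TreeView(const List &tree)
      : var(as<IntegerVector>(tree["var"])),
        left(as<IntegerVector>(tree["left"])),
        right(as<IntegerVector>(tree["right"])),
        thr(as<NumericVector>(tree["threshold"])) {}
  int route(const NumericMatrix &X, int row) const {
    int node = 0;
    while (var[node] != NA_INTEGER)
      node = (X(row, var[node] - 1) <= thr[node]) ? left[node] - 1
                                                  : right[node] - 1;
    return node;
  }
};

// Average per-leaf estimation statistics over (optionally OOB) trees.
// target_ids: 1-based training row ids, or 0 for out-of-sample profiles.
// [[Rcpp::export]]
List cpp_accumulate(List trees, NumericMatrix Xtarget, IntegerVector target_ids,
                    bool oob, int n_train) {
  const int nt = trees.size();
  const int m = Xtarget.nrow();
  NumericMatrix acc(m, 5);
  IntegerVector count(m);
  std::vector<char> inbag((size_t)n_train, 0);

  for (int t = 0; t < nt; ++t) {
    List tree = trees[t];
    TreeView tv(tree);
    NumericMatrix stats = as<NumericMatrix>(tree["stats"]);
    if (oob) {
      std::fill(inbag.begin(), inbag.end(), 0);
      IntegerVector sub = tree["subsample"];
      for (int i = 0; i < sub.size(); ++i) inbag[sub[i] - 1] = 1;
    }
    for (int j = 0; j < m; ++j) {
      if (oob && target_ids[j] > 0 && inbag[target_ids[j] - 1]) continue;
      int leaf = tv.route(Xtarget, j);
      if (NumericVector::is_na(stats(leaf, 0))) continue; // empty-est leaf
      for (int k = 0; k < 5; ++k) acc(j, k) += stats(leaf, k);
      count[j] += 1;
    }
  }
  for (int j = 0; j < m; ++j)
    if (count[j] > 0)
      for (int k = 0; k < 5; ++k) acc(j, k) /= (double)count[j];
  return List::create(_["stats"] = acc, _["count"] = count);
}

// Explicit similarity weights alpha_i(x): average over (OOB) trees of
// 1{i in target's leaf, estimation half} / leaf estimation size.
// [[Rcpp::export]]
NumericMatrix cpp_forest_weights(List trees, NumericMatrix Xtrain,
                                 NumericMatrix Xtarget, IntegerVector target_ids,
                                 bool oob) {
  const int nt = trees.size();
  const int m = Xtarget.nrow();
  const int n = Xtrain.nrow();
  NumericMatrix W(m, n);
  IntegerVector count(m);
  std::vector<char> inbag((size_t)n, 0);
  std::vector<int> leaf_of_est;

  for (int t = 0; t < nt; ++t) {
    List tree = trees[t];
    TreeView tv(tree);
    IntegerVector est = tree["est_units"];
    leaf_of_est.assign(est.size(), -1);
    // leaf -> estimation members (count leaf sizes first)
    std::vector<int> leaf_size(tv.var.size(), 0);
    for (int i = 0; i < est.size(); ++i) {
      int lf = tv.route(Xtrain, est[i] - 1);
      leaf_of_est[i] = lf;
      leaf_size[lf] += 1;
    }
    if (oob) {
      std::fill(inbag.begin(), inbag.end(), 0);
      IntegerVector sub = tree["subsample"];
      for (int i = 0; i < sub.size(); ++i) inbag[sub[i] - 1] = 1;
    }
    for (int j = 0; j < m; ++j) {
      if (oob && target_ids[j] > 0 && inbag[target_ids[j] - 1]) continue;
      int lf = tv.route(Xtarget, j);
      if (leaf_size[lf] == 0) continue;
      for (int i = 0; i < est.size(); ++i)
        if (leaf_of_est[i] == lf)
          W(j, est[i] - 1) += 1.0 / (double)leaf_size[lf];
      count[j] += 1;
    }
  }
  for (int j = 0; j < m; ++j)
    if (count[j] > 0)
      for (int i = 0; i < n; ++i) W(j, i) /= (double)count[j];
  return W;
}

// Leaf id (1-based node index) each target row reaches in each tree.
// [[Rcpp::export]]
IntegerMatrix cpp_leaf_ids(List trees, NumericMatrix Xtarget) {
  const int nt = trees.size();
  const int m = Xtarget.nrow();
  IntegerMatrix L(m, nt);
  for (int t = 0; t < nt; ++t) {
    TreeView tv(trees[t]);
    for (int j = 0; j < m; ++j) L(j, t) = tv.route(Xtarget, j) + 1;
  }
  return L;
}
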