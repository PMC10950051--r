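#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classification trees with curvature-test split-variable selection and
// surrogate splits for missing predictor values. Missing values are NA_REAL
// in the predictor matrix. Rows whose primary split value and every
// surrogate value are missing are not passed to children: at training time
// they contribute to the node posterior only, and at prediction time the
// node posterior is returned for them.

static const double EPS = 1e-12;

// type-7 quantile of a sorted array of values
static double quantile7(const std::vector<std::pair<double, int> > &v, double p) {
  const int m = (int)v.size();
  if (m == 1) return v[0].first;
  double h = (m - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= m - 1) return v[m - 1].first;
  return v[lo].first + (h - lo) * (v[lo + 1].first - v[lo].first);
}

// Pearson chi-square upper-tail p from a weighted contingency table
// (nr x nc, row-major); empty rows/columns are dropped first.
static double chisq_p_table(const std::vector<double> &tab, int nr, int nc) {
  std::vector<double> rs(nr, 0.0), cs(nc, 0.0);
  double tot = 0.0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      rs[r] += tab[r * nc + c];
      cs[c] += tab[r * nc + c];
      tot += tab[r * nc + c];
    }
  int R2 = 0, C2 = 0;
  for (int r = 0; r < nr; ++r) if (rs[r] > 0) ++R2;
  for (int c = 0; c < nc; ++c) if (cs[c] > 0) ++C2;
  if (R2 < 2 || C2 < 2 || tot <= 0) return 1.0;
  double chi2 = 0.0;
  for (int r = 0; r < nr; ++r) {
    if (rs[r] <= 0) continue;
    for (int c = 0; c < nc; ++c) {
      if (cs[c] <= 0) continue;
      double e = rs[r] * cs[c] / tot;
      double d = tab[r * nc + c] - e;
      chi2 += d * d / e;
    }
  }
  int df = (R2 - 1) * (C2 - 1);
  return R::pchisq(chi2, (double)df, 0, 0);
}

// quartile bin edges from a sorted (value,row) array (duplicates collapsed,
// edges that would leave an empty top bin dropped)
static std::vector<double> quartile_breaks(
    const std::vector<std::pair<double, int> > &sv) {
  std::vector<double> br;
  for (double p : {0.25, 0.5, 0.75}) {
    double q = quantile7(sv, p);
    if (br.empty() || q > br.back() + EPS) br.push_back(q);
  }
  std::vector<double> out;
  for (double b : br)
    if (b < sv.back().first - EPS) out.push_back(b);
  return out;
}

static inline int bin_of(double x, const std::vector<double> &br) {
  int b = 0;
  for (double e : br) {
    if (x <= e) break;
    ++b;
  }
  return b;
}

// curvature test from the node's sorted present values of one variable
static double curvature_p_sorted(const std::vector<std::pair<double, int> > &sv,
                                 const int *y, const double *w, int K) {
  if (sv.size() < 2) return 1.0;
  std::vector<double> br = quartile_breaks(sv);
  int nb = (int)br.size() + 1;
  if (nb < 2) return 1.0;
  std::vector<double> tab(nb * K, 0.0);
  int b = 0;
  for (const auto &pr : sv) {
    while (b + 1 < nb && pr.first > br[b]) ++b; // sorted: bins advance
    tab[b * K + y[pr.second]] += w[pr.second];
  }
  return chisq_p_table(tab, nb, K);
}

// interaction curvature test (joint bins of two variables vs class) over
// rows where both are present
static double interaction_p_rows(const double *xj1, const double *xj2,
                                 const std::vector<int> &rows, const int *y,
                                 const double *w, int K) {
  std::vector<std::pair<double, int> > s1, s2;
  for (int i : rows)
    if (!ISNAN(xj1[i]) && !ISNAN(xj2[i])) {
      s1.push_back(std::make_pair(xj1[i], i));
      s2.push_back(std::make_pair(xj2[i], i));
    }
  if (s1.size() < 2) return 1.0;
  std::sort(s1.begin(), s1.end());
  std::sort(s2.begin(), s2.end());
  std::vector<double> b1 = quartile_breaks(s1), b2 = quartile_breaks(s2);
  int n1 = (int)b1.size() + 1, n2 = (int)b2.size() + 1;
  if (n1 * n2 < 2) return 1.0;
  std::vector<double> tab(n1 * n2 * K, 0.0);
  for (const auto &pr : s1) {
    int i = pr.second;
    int cell = bin_of(xj1[i], b1) * n2 + bin_of(xj2[i], b2);
    tab[cell * K + y[i]] += w[i];
  }
  return chisq_p_table(tab, n1 * n2, K);
}

// [[Rcpp::export]]
double cpp_curvature_p(NumericMatrix X, int j, IntegerVector y,
                       NumericVector w, int K) {
  const double *xj = &X(0, j - 1);
  std::vector<std::pair<double, int> > sv;
  for (int i = 0; i < X.nrow(); ++i)
    if (!ISNAN(xj[i])) sv.push_back(std::make_pair(xj[i], i));
  if (sv.empty()) return 1.0;
  std::sort(sv.begin(), sv.end());
  return curvature_p_sorted(sv, y.begin(), w.begin(), K);
}

// [[Rcpp::export]]
double cpp_interaction_p(NumericMatrix X, int j1, int j2, IntegerVector y,
                         NumericVector w, int K) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  return interaction_p_rows(&X(0, j1 - 1), &X(0, j2 - 1), rows, y.begin(),
                            w.begin(), K);
}

struct CutResult {
  bool ok;
  double thr;
  double gain;
};

static inline double gini_of(const std::vector<double> &cls, double tot) {
  if (tot <= 0) return 0.0;
  double g = 1.0;
  for (double c : cls) g -= (c / tot) * (c / tot);
  return g;
}

// best Gini-gain cut from the sorted present values; min_leaf counted in
// observations on each side of the present rows
static CutResult best_gini_cut(const std::vector<std::pair<double, int> > &sv,
                               const int *y, const double *w, int K,
                               int min_leaf) {
  CutResult res = {false, 0.0, 0.0};
  int m = (int)sv.size();
  if (m < 2 * min_leaf) return res;
  std::vector<double> totc(K, 0.0), leftc(K, 0.0);
  double wtot = 0.0, wleft = 0.0;
  for (int t = 0; t < m; ++t) {
    totc[y[sv[t].second]] += w[sv[t].second];
    wtot += w[sv[t].second];
  }
  double g0 = gini_of(totc, wtot);
  double best = EPS;
  for (int t = 0; t < m - 1; ++t) {
    int i = sv[t].second;
    leftc[y[i]] += w[i];
    wleft += w[i];
    if (t + 1 < min_leaf || m - t - 1 < min_leaf) continue;
    if (sv[t + 1].first <= sv[t].first + EPS) continue;
    double gr = 1.0, gl = 1.0;
    for (int c = 0; c < K; ++c) {
      double fl = leftc[c] / wleft, fr = (totc[c] - leftc[c]) / (wtot - wleft);
      gl -= fl * fl;
      gr -= fr * fr;
    }
    double gain = g0 - (wleft / wtot) * gl - ((wtot - wleft) / wtot) * gr;
    if (gain > best) {
      best = gain;
      res.ok = true;
      res.thr = 0.5 * (sv[t].first + sv[t + 1].first);
      res.gain = gain;
    }
  }
  return res;
}

struct Surrogate {
  int var;
  double thr;
  int dir; // +1: x <= thr goes left (as primary); -1: x <= thr goes right
  double agree;
};

// best agreeing cut on one variable (its sorted present values) against the
// primary left/right assignment; side[i] in {0 left, 1 right, -1 not primary}
static bool best_surrogate(const std::vector<std::pair<double, int> > &sv,
                           const signed char *side, const double *w,
                           Surrogate &out) {
  double wtot = 0.0, wl_tot = 0.0;
  int m = 0;
  for (const auto &pr : sv) {
    if (side[pr.second] < 0) continue;
    ++m;
    wtot += w[pr.second];
    if (side[pr.second] == 0) wl_tot += w[pr.second];
  }
  if (m < 2 || wtot <= 0) return false;
  double bestA = 0.5, cumL = 0.0, cumW = 0.0;
  bool found = false;
  int seen = 0;
  double prev = 0.0;
  for (size_t t = 0; t < sv.size(); ++t) {
    int i = sv[t].second;
    if (side[i] < 0) continue;
    if (seen > 0 && sv[t].first > prev + EPS && seen < m) {
      // candidate cut between prev and current value
      double a1 = (cumL + (wtot - wl_tot) - (cumW - cumL)) / wtot;
      double a = std::max(a1, 1.0 - a1);
      if (a > bestA + EPS) {
        bestA = a;
        out.thr = 0.5 * (prev + sv[t].first);
        out.dir = (a1 >= 1.0 - a1) ? 1 : -1;
        out.agree = a;
        found = true;
      }
    }
    cumW += w[i];
    if (side[i] == 0) cumL += w[i];
    prev = sv[t].first;
    ++seen;
  }
  return found;
}

struct Tree {
  std::vector<int> var, left, right, is_leaf, obs;
  std::vector<double> thr, risk_red, wnode;
  std::vector<double> post; // n_nodes x K
  std::vector<int> surr_start, surr_n;
  std::vector<int> surr_var, surr_dir;
  std::vector<double> surr_thr, surr_agree;
};

struct QItem {
  int node;
  std::vector<int> rows;
};

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, NumericVector w, int K,
                   int min_leaf, int max_splits, int n_surrogates) {
  const int p = X.ncol(), n = X.nrow();
  const double *xp = X.begin();
  const int *yp = y.begin();
  const double *wp = w.begin();
  Tree tr;
  double wtotal = 0.0;
  for (int i = 0; i < n; ++i) wtotal += wp[i];

  std::vector<QItem> queue;
  {
    QItem root;
    root.node = 0;
    for (int i = 0; i < n; ++i)
      if (wp[i] > 0) root.rows.push_back(i);
    queue.push_back(root);
  }
  auto alloc_node = [&]() {
    tr.var.push_back(-1);
    tr.thr.push_back(NA_REAL);
    tr.left.push_back(-1);
    tr.right.push_back(-1);
    tr.is_leaf.push_back(1);
    tr.obs.push_back(0);
    tr.wnode.push_back(0.0);
    tr.risk_red.push_back(0.0);
    tr.surr_start.push_back(0);
    tr.surr_n.push_back(0);
    for (int c = 0; c < K; ++c) tr.post.push_back(0.0);
    return (int)tr.var.size() - 1;
  };
  alloc_node();

  std::vector<signed char> side(n, -1);
  std::vector<std::vector<std::pair<double, int> > > sorted(p);
  int splits_used = 0;
  size_t qi = 0;
  while (qi < queue.size()) {
    QItem it = queue[qi++];
    int nid = it.node;
    const std::vector<int> &rows = it.rows;
    std::vector<double> cls(K, 0.0);
    double wn = 0.0;
    for (int i : rows) {
      cls[yp[i]] += wp[i];
      wn += wp[i];
    }
    tr.obs[nid] = (int)rows.size();
    tr.wnode[nid] = wn;
    for (int c = 0; c < K; ++c) tr.post[nid * K + c] = wn > 0 ? cls[c] / wn : 1.0 / K;
    bool pure = false;
    for (int c = 0; c < K; ++c)
      if (cls[c] >= wn - EPS && wn > 0) pure = true;
    if (pure || (int)rows.size() < 2 * min_leaf || splits_used >= max_splits)
      continue;
    // sort each variable's present values once for this node; reused by the
    // curvature test, the Gini cut search and the surrogate search
    for (int j = 0; j < p; ++j) {
      sorted[j].clear();
      const double *xj = xp + (size_t)j * n;
      for (int i : rows)
        if (!ISNAN(xj[i])) sorted[j].push_back(std::make_pair(xj[i], i));
      std::sort(sorted[j].begin(), sorted[j].end());
    }
    // curvature-test split-variable selection
    std::vector<double> pvals(p, 1.0);
    double pmin = 1.0;
    for (int j = 0; j < p; ++j) {
      pvals[j] = curvature_p_sorted(sorted[j], yp, wp, K);
      if (pvals[j] < pmin) pmin = pvals[j];
    }
    if (pmin >= 1.0 - EPS) continue; // nothing informative
    std::vector<int> tied;
    for (int j = 0; j < p; ++j)
      if (pvals[j] <= pmin + 1e-12) tied.push_back(j);
    int jbest = tied[0];
    if (tied.size() > 1) {
      // refine exact ties by the pairwise interaction test
      double best_ip = 2.0;
      for (int j : tied) {
        double ipmin = 1.0;
        for (int k2 : tied) {
          if (k2 == j) continue;
          double ip = interaction_p_rows(xp + (size_t)j * n,
                                         xp + (size_t)k2 * n, rows, yp, wp, K);
          if (ip < ipmin) ipmin = ip;
        }
        if (ipmin < best_ip - 1e-12) {
          best_ip = ipmin;
          jbest = j;
        }
      }
    }
    CutResult cut = best_gini_cut(sorted[jbest], yp, wp, K, min_leaf);
    if (!cut.ok) continue; // no admissible split -> leaf
    // primary assignment for rows with the split variable present
    for (int i : rows) side[i] = -1;
    for (const auto &pr : sorted[jbest])
      side[pr.second] = pr.first <= cut.thr ? 0 : 1;
    // surrogates
    std::vector<Surrogate> surr;
    for (int k2 = 0; k2 < p; ++k2) {
      if (k2 == jbest) continue;
      Surrogate s;
      s.var = k2;
      if (best_surrogate(sorted[k2], side.data(), wp, s) && s.agree > 0.5)
        surr.push_back(s);
    }
    std::stable_sort(surr.begin(), surr.end(),
                     [](const Surrogate &a, const Surrogate &b) {
                       if (a.agree != b.agree) return a.agree > b.agree;
                       return a.var < b.var;
                     });
    if ((int)surr.size() > n_surrogates) surr.resize(n_surrogates);
    // route rows: primary value, else surrogates in agreement order, else
    // the row stays at this node
    std::vector<int> lrows, rrows;
    for (int i : rows) {
      int s2 = side[i];
      if (s2 < 0) {
        for (const Surrogate &s : surr) {
          double xs = xp[(size_t)s.var * n + i];
          if (ISNAN(xs)) continue;
          bool le = xs <= s.thr;
          s2 = (s.dir == 1) ? (le ? 0 : 1) : (le ? 1 : 0);
          break;
        }
      }
      if (s2 == 0) lrows.push_back(i);
      else if (s2 == 1) rrows.push_back(i);
    }
    for (int i : rows) side[i] = -1;
    if ((int)lrows.size() < min_leaf || (int)rrows.size() < min_leaf) continue;
    // risk reduction (weighted Gini risk relative to total weight)
    auto risk = [&](const std::vector<int> &rr) {
      std::vector<double> cc(K, 0.0);
      double ww = 0.0;
      for (int i : rr) {
        cc[yp[i]] += wp[i];
        ww += wp[i];
      }
      return (ww / wtotal) * gini_of(cc, ww);
    };
    double rr = risk(rows) - risk(lrows) - risk(rrows);
    ++splits_used;
    tr.var[nid] = jbest;
    tr.thr[nid] = cut.thr;
    tr.is_leaf[nid] = 0;
    tr.risk_red[nid] = rr > 0 ? rr : 0.0;
    tr.surr_start[nid] = (int)tr.surr_var.size();
    tr.surr_n[nid] = (int)surr.size();
    for (const Surrogate &s : surr) {
      tr.surr_var.push_back(s.var);
      tr.surr_thr.push_back(s.thr);
      tr.surr_dir.push_back(s.dir);
      tr.surr_agree.push_back(s.agree);
    }
    int lid = alloc_node(), rid = alloc_node();
    tr.left[nid] = lid;
    tr.right[nid] = rid;
    QItem li, ri;
    li.node = lid;
    li.rows = std::move(lrows);
    ri.node = rid;
    ri.rows = std::move(rrows);
    queue.push_back(std::move(li));
    queue.push_back(std::move(ri));
  }

  int nn = (int)tr.var.size();
  NumericMatrix post(nn, K);
  for (int n2 = 0; n2 < nn; ++n2)
    for (int c = 0; c < K; ++c) post(n2, c) = tr.post[n2 * K + c];
  return List::create(
      _["var"] = wrap(tr.var), _["threshold"] = wrap(tr.thr),
      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
      _["is_leaf"] = wrap(tr.is_leaf), _["posterior"] = post,
      _["n_obs"] = wrap(tr.obs), _["w_node"] = wrap(tr.wnode),
      _["risk_reduction"] = wrap(tr.risk_red),
      _["surr_start"] = wrap(tr.surr_start), _["surr_n"] = wrap(tr.surr_n),
      _["surr_var"] = wrap(tr.surr_var), _["surr_threshold"] = wrap(tr.surr_thr),
      _["surr_dir"] = wrap(tr.surr_dir), _["surr_agreement"] = wrap(tr.surr_agree),
      _["n_classes"] = K);
}

// unpacked tree view for fast routing
struct TreeView {
  const int *var, *left, *right, *is_leaf, *sstart, *sn, *svar, *sdir;
  const double *thr, *sthr;
  int K;
  // keep extracted vectors alive
  IntegerVector v1, v2, v3, v4, v5, v6, v7, v8;
  NumericVector d1, d2;
  explicit TreeView(const List &tree) {
    v1 = tree["var"]; v2 = tree["left"]; v3 = tree["right"];
    v4 = tree["is_leaf"]; v5 = tree["surr_start"]; v6 = tree["surr_n"];
    v7 = tree["surr_var"]; v8 = tree["surr_dir"];
    d1 = tree["threshold"]; d2 = tree["surr_threshold"];
    var = v1.begin(); left = v2.begin(); right = v3.begin();
    is_leaf = v4.begin(); sstart = v5.begin(); sn = v6.begin();
    svar = v7.length() ? v7.begin() : nullptr;
    sdir = v8.length() ? v8.begin() : nullptr;
    thr = d1.begin();
    sthr = d2.length() ? d2.begin() : nullptr;
    K = as<int>(tree["n_classes"]);
  }
};

// route one row; returns the node where it lands (leaf, or the deepest node
// reached when the primary and all surrogate values are missing)
static int route_row(const TreeView &tv, const double *xp, int n, int i) {
  int nid = 0;
  while (!tv.is_leaf[nid]) {
    double x = xp[(size_t)tv.var[nid] * n + i];
    int s2 = -1;
    if (!ISNAN(x)) s2 = (x <= tv.thr[nid]) ? 0 : 1;
    else {
      for (int s = tv.sstart[nid]; s < tv.sstart[nid] + tv.sn[nid]; ++s) {
        double xs = xp[(size_t)tv.svar[s] * n + i];
        if (ISNAN(xs)) continue;
        bool le = xs <= tv.sthr[s];
        s2 = (tv.sdir[s] == 1) ? (le ? 0 : 1) : (le ? 1 : 0);
        break;
      }
    }
    if (s2 < 0) return nid; // value ignored: stop here
    nid = (s2 == 0) ? tv.left[nid] : tv.right[nid];
  }
  return nid;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_tree(List tree, NumericMatrix X) {
  TreeView tv(tree);
  NumericMatrix post = tree["posterior"];
  const int n = X.nrow();
  NumericMatrix out(n, tv.K);
  for (int i = 0; i < n; ++i) {
    int nid = route_row(tv, X.begin(), n, i);
    for (int c = 0; c < tv.K; ++c) out(i, c) = post(nid, c);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_leaf_of(List tree, NumericMatrix X) {
  TreeView tv(tree);
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = route_row(tv, X.begin(), n, i) + 1;
  return out;
}

// accumulate boosting votes: score += alpha * (2 * argmax-is-class-2 - 1)
// [[Rcpp::export]]
NumericVector cpp_boost_scores(List trees, NumericVector alphas,
                               NumericMatrix X) {
  const int n = X.nrow();
  NumericVector score(n);
  for (int b = 0; b < trees.size(); ++b) {
    List tree = trees[b];
    TreeView tv(tree);
    NumericMatrix post = tree["posterior"];
    for (int i = 0; i < n; ++i) {
      int nid = route_row(tv, X.begin(), n, i);
      score[i] += alphas[b] * (post(nid, 1) > post(nid, 0) ? 1.0 : -1.0);
    }
  }
  return score;
}

// mean posterior over a bagged ensemble
// [[Rcpp::export]]
NumericMatrix cpp_bag_posterior(List trees, NumericMatrix X) {
  const int n = X.nrow();
  List tree0 = trees[0];
  int K = as<int>(tree0["n_classes"]);
  NumericMatrix out(n, K);
  for (int b = 0; b < trees.size(); ++b) {
    List tree = trees[b];
    TreeView tv(tree);
    NumericMatrix post = tree["posterior"];
    for (int i = 0; i < n; ++i) {
      int nid = route_row(tv, X.begin(), n, i);
      for (int c = 0; c < K; ++c) out(i, c) += post(nid, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < K; ++c) out(i, c) /= trees.size();
  return out;
}

// bottom-up collapse of subtrees whose removal does not increase the
// validation misclassification count
// [[Rcpp::export]]
List cpp_prune_tree(List tree, NumericMatrix Xval, IntegerVector yval) {
  IntegerVector var = clone(as<IntegerVector>(tree["var"]));
  IntegerVector left = clone(as<IntegerVector>(tree["left"]));
  IntegerVector right = clone(as<IntegerVector>(tree["right"]));
  IntegerVector is_leaf = clone(as<IntegerVector>(tree["is_leaf"]));
  IntegerVector surr_n = clone(as<IntegerVector>(tree["surr_n"]));
  NumericMatrix post = tree["posterior"];
  TreeView tv(tree);
  int K = tv.K;
  int nn = var.size();
  const int n = Xval.nrow();
  std::vector<int> node_class(nn, 0);
  for (int n2 = 0; n2 < nn; ++n2) {
    double best = -1.0;
    for (int c = 0; c < K; ++c)
      if (post(n2, c) > best) {
        best = post(n2, c);
        node_class[n2] = c;
      }
  }
  // route validation rows, tallying reach errors and early-stop errors
  std::vector<double> reach_err(nn, 0.0), stop_err(nn, 0.0);
  const double *xp = Xval.begin();
  for (int i = 0; i < n; ++i) {
    int nid = 0;
    while (true) {
      if (node_class[nid] != yval[i]) reach_err[nid] += 1.0;
      if (tv.is_leaf[nid]) break;
      double x = xp[(size_t)tv.var[nid] * n + i];
      int s2 = -1;
      if (!ISNAN(x)) s2 = (x <= tv.thr[nid]) ? 0 : 1;
      else {
        for (int s = tv.sstart[nid]; s < tv.sstart[nid] + tv.sn[nid]; ++s) {
          double xs = xp[(size_t)tv.svar[s] * n + i];
          if (ISNAN(xs)) continue;
          bool le = xs <= tv.sthr[s];
          s2 = (tv.sdir[s] == 1) ? (le ? 0 : 1) : (le ? 1 : 0);
          break;
        }
      }
      if (s2 < 0) {
        if (node_class[nid] != yval[i]) stop_err[nid] += 1.0;
        break;
      }
      nid = (s2 == 0) ? tv.left[nid] : tv.right[nid];
    }
  }
  // nodes are allocated in breadth-first order: children have larger ids
  std::vector<double> sub_err(nn, 0.0);
  for (int n2 = nn - 1; n2 >= 0; --n2) {
    if (is_leaf[n2]) {
      sub_err[n2] = reach_err[n2];
      continue;
    }
    sub_err[n2] = stop_err[n2] + sub_err[left[n2]] + sub_err[right[n2]];
    if (reach_err[n2] <= sub_err[n2]) {
      is_leaf[n2] = 1;
      left[n2] = -1;
      right[n2] = -1;
      var[n2] = -1;
      surr_n[n2] = 0;
      sub_err[n2] = reach_err[n2];
    }
  }
  List out = clone(tree);
  out["var"] = var;
  out["left"] = left;
  out["right"] = right;
  out["is_leaf"] = is_leaf;
  out["surr_n"] = surr_n;
  return out;
}
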