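// Survival random forest: bootstrap-aggregated survival trees with
// log-rank splitting and Nelson-Aalen terminal-node cumulative hazards.
// Trees are stored flat (forest-level arrays); leaves keep their CHF as a
// sparse (time, increment) step function, so evaluation at any horizon is
// exact.  Randomness comes from R's RNG (seed with set.seed() in R).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct ForestBuf {
  std::vector<int> svar, left, right;      // per node; svar = -1 for leaf
  std::vector<double> sval;
  std::vector<int> loff, llen;             // per node: leaf CHF slice
  std::vector<double> ltime, linc;         // forest-level leaf CHF storage
};

struct Problem {
  const int *X;                 // n x p, column-major
  const double *time;
  const int *status;
  int n, p, mtry, nodesize;
};

int rand_int(int n) {           // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// log-rank chi-square for split "x <= thr" among node members (sorted by
// time ascending).  Returns statistic, and child sizes via out params.
double logrank_stat(const Problem &pr, const std::vector<int> &idx, int var,
                    double thr, int &n_left, int &n_right) {
  const int m = (int)idx.size();
  int m1 = 0;
  for (int k = 0; k < m; ++k)
    if (pr.X[var * pr.n + idx[k]] <= thr) ++m1;
  n_left = m1;
  n_right = m - m1;
  if (m1 == 0 || m1 == m) return -1.0;
  double num = 0.0, den = 0.0;
  int at_risk = m, at_risk1 = m1;
  int k = 0;
  while (k < m) {
    double t = pr.time[idx[k]];
    int d = 0, d1 = 0, grp = 0, grp1 = 0;
    int j = k;
    for (; j < m && pr.time[idx[j]] == t; ++j) {
      bool inL = pr.X[var * pr.n + idx[j]] <= thr;
      if (pr.status[idx[j]]) { ++d; if (inL) ++d1; }
      ++grp; if (inL) ++grp1;
    }
    if (d > 0 && at_risk > 1) {
      double p1 = (double)at_risk1 / at_risk;
      num += d1 - d * p1;
      den += d * p1 * (1.0 - p1) * (double)(at_risk - d) / (at_risk - 1);
    }
    at_risk -= grp;
    at_risk1 -= grp1;
    k = j;
  }
  if (den <= 0.0) return -1.0;
  return num * num / den;
}

void make_leaf(ForestBuf &fb, const Problem &pr, const std::vector<int> &idx,
               int node) {
  fb.svar[node] = -1;
  fb.sval[node] = 0.0;
  fb.left[node] = fb.right[node] = -1;
  fb.loff[node] = (int)fb.ltime.size();
  const int m = (int)idx.size();
  int at_risk = m, k = 0, len = 0;
  while (k < m) {
    double t = pr.time[idx[k]];
    int d = 0, grp = 0, j = k;
    for (; j < m && pr.time[idx[j]] == t; ++j) {
      if (pr.status[idx[j]]) ++d;
      ++grp;
    }
    if (d > 0) {
      fb.ltime.push_back(t);
      fb.linc.push_back((double)d / at_risk);
      ++len;
    }
    at_risk -= grp;
    k = j;
  }
  fb.llen[node] = len;
}

int new_node(ForestBuf &fb) {
  fb.svar.push_back(0); fb.sval.push_back(0.0);
  fb.left.push_back(-1); fb.right.push_back(-1);
  fb.loff.push_back(-1); fb.llen.push_back(0);
  return (int)fb.svar.size() - 1;
}

// idx must be sorted by time ascending; partition preserves order.
int build_node(ForestBuf &fb, const Problem &pr, std::vector<int> &idx,
               std::vector<int> &feat_pool) {
  int node = new_node(fb);
  const int m = (int)idx.size();
  int deaths = 0;
  for (int k = 0; k < m; ++k) deaths += pr.status[idx[k]];
  if (m < 2 * pr.nodesize || deaths == 0) {
    make_leaf(fb, pr, idx, node);
    return node;
  }
  // draw mtry candidate features without replacement
  int p = pr.p;
  for (int k = 0; k < p; ++k) feat_pool[k] = k;
  int tries = std::min(pr.mtry, p);
  double best = 0.0, best_thr = 0.0;
  int best_var = -1;
  for (int k = 0; k < tries; ++k) {
    int pick = k + rand_int(p - k);
    std::swap(feat_pool[k], feat_pool[pick]);
    int var = feat_pool[k];
    // unique sorted values in node
    std::vector<double> vals(m);
    for (int j = 0; j < m; ++j) vals[j] = pr.X[var * pr.n + idx[j]];
    std::sort(vals.begin(), vals.end());
    vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
    for (size_t v = 0; v + 1 < vals.size(); ++v) {
      int nl, nr;
      double st = logrank_stat(pr, idx, var, vals[v], nl, nr);
      if (st > best && nl >= pr.nodesize && nr >= pr.nodesize) {
        best = st; best_var = var; best_thr = vals[v];
      }
    }
  }
  if (best_var < 0) {
    make_leaf(fb, pr, idx, node);
    return node;
  }
  std::vector<int> li, ri;
  li.reserve(m); ri.reserve(m);
  for (int k = 0; k < m; ++k) {
    if (pr.X[best_var * pr.n + idx[k]] <= best_thr) li.push_back(idx[k]);
    else ri.push_back(idx[k]);
  }
  fb.svar[node] = best_var;
  fb.sval[node] = best_thr;
  int lc = build_node(fb, pr, li, feat_pool);
  int rc = build_node(fb, pr, ri, feat_pool);
  fb.left[node] = lc;
  fb.right[node] = rc;
  return node;
}

int drop_down(const ForestBuf &fb, int root, const int *Xrow, int n_stride) {
  int node = root;
  while (fb.svar[node] >= 0) {
    node = (Xrow[fb.svar[node] * n_stride] <= fb.sval[node])
         ? fb.left[node] : fb.right[node];
  }
  return node;
}

// add leaf CHF evaluated at sorted eval_times to row `row` of out (n_out x K)
void add_leaf_chf(const ForestBuf &fb, int leaf, const NumericVector &ev,
                  double *out, int row, int n_out) {
  int off = fb.loff[leaf], len = fb.llen[leaf];
  double h = 0.0;
  int j = 0;
  for (int k = 0; k < ev.size(); ++k) {
    while (j < len && fb.ltime[off + j] <= ev[k]) h += fb.linc[off + j++];
    out[k * n_out + row] += h;
  }
}

} // namespace

// [[Rcpp::export]]
List srf_fit_cpp(IntegerMatrix X, NumericVector time, IntegerVector status,
                 int ntree, int mtry, int nodesize, NumericVector eval_times) {
  const int n = X.nrow(), p = X.ncol();
  Problem pr{&X[0], &time[0], &status[0], n, p, mtry, std::max(1, nodesize)};
  ForestBuf fb;
  std::vector<int> roots(ntree), feat_pool(p);
  const int K = eval_times.size();
  NumericMatrix oob_chf(n, K);
  IntegerVector oob_count(n);
  std::vector<int> order_by_time(n);
  for (int i = 0; i < n; ++i) order_by_time[i] = i;
  std::sort(order_by_time.begin(), order_by_time.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  std::vector<int> rank_of(n);
  for (int i = 0; i < n; ++i) rank_of[order_by_time[i]] = i;
  std::vector<int> inbag(n), boot, idx;
  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    boot.clear();
    for (int i = 0; i < n; ++i) {
      int pick = rand_int(n);
      boot.push_back(pick);
      inbag[pick]++;
    }
    // sort bootstrap members by time (stable via rank)
    std::sort(boot.begin(), boot.end(),
              [&](int a, int b) { return rank_of[a] < rank_of[b]; });
    idx = boot;
    roots[t] = build_node(fb, pr, idx, feat_pool);
    for (int i = 0; i < n; ++i) {
      if (inbag[i]) continue;
      int leaf = drop_down(fb, roots[t], &X[0] + i, n);
      add_leaf_chf(fb, leaf, eval_times, &oob_chf[0], i, n);
      oob_count[i]++;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (oob_count[i] > 0)
      for (int k = 0; k < K; ++k) oob_chf(i, k) /= oob_count[i];
    else
      for (int k = 0; k < K; ++k) oob_chf(i, k) = NA_REAL;
  }
  return List::create(
    _["roots"] = IntegerVector(roots.begin(), roots.end()),
    _["svar"] = IntegerVector(fb.svar.begin(), fb.svar.end()),
    _["sval"] = NumericVector(fb.sval.begin(), fb.sval.end()),
    _["left"] = IntegerVector(fb.left.begin(), fb.left.end()),
    _["right"] = IntegerVector(fb.right.begin(), fb.right.end()),
    _["loff"] = IntegerVector(fb.loff.begin(), fb.loff.end()),
    _["llen"] = IntegerVector(fb.llen.begin(), fb.llen.end()),
    _["ltime"] = NumericVector(fb.ltime.begin(), fb.ltime.end()),
    _["linc"] = NumericVector(fb.linc.begin(), fb.linc.end()),
    _["oob_chf"] = oob_chf,
    _["oob_count"] = oob_count);
}

// [[Rcpp::export]]
NumericMatrix srf_predict_cpp(List forest, IntegerMatrix X,
                              NumericVector eval_times) {
  ForestBuf fb;
  IntegerVector roots = forest["roots"];
  IntegerVector svar = forest["svar"], left = forest["left"],
                right = forest["right"], loff = forest["loff"],
                llen = forest["llen"];
  NumericVector sval = forest["sval"], ltime = forest["ltime"],
                linc = forest["linc"];
  fb.svar.assign(svar.begin(), svar.end());
  fb.sval.assign(sval.begin(), sval.end());
  fb.left.assign(left.begin(), left.end());
  fb.right.assign(right.begin(), right.end());
  fb.loff.assign(loff.begin(), loff.end());
  fb.llen.assign(llen.begin(), llen.end());
  fb.ltime.assign(ltime.begin(), ltime.end());
  fb.linc.assign(linc.begin(), linc.end());
  const int n = X.nrow(), K = eval_times.size(), ntree = roots.size();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < ntree; ++t) {
      int leaf = drop_down(fb, roots[t], &X[0] + i, n);
      add_leaf_chf(fb, leaf, eval_times, &out[0], i, n);
    }
    for (int k = 0; k < K; ++k) out(i, k) /= ntree;
  }
  return out;
}
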