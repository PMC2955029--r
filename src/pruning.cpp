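// Felsenstein pruning for reversible 4-state models with discrete rate
// categories.  The model reaches C++ pre-diagonalised: P(t) = U1 exp(L t) U2,
// where U1/U2 absorb the sqrt(pi) symmetrisation of the rate matrix.  An
// invariant-sites class is just a category with rate 0.  Trees arrive as an
// ape edge matrix in postorder (children listed before their parent's own
// edge), with the (possibly trifurcating) root at node n_tip + 1.
//
// No likelihood rescaling is performed: with <= a few dozen taxa per-site
// likelihoods stay far above the double underflow threshold.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void edge_pmat(const NumericMatrix &U1, const NumericMatrix &U2,
                      const NumericVector &lam, double t, double P[4][4]) {
  double e[4];
  for (int i = 0; i < 4; ++i) e[i] = std::exp(lam[i] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += U1(i, k) * e[k] * U2(k, j);
      P[i][j] = s > 0.0 ? s : 0.0;  // clip tiny negatives from roundoff
    }
}

// Per-pattern log-likelihoods, mixing over rate categories.
static void site_lik_core(const IntegerMatrix &edge, int n_tip, int n_node,
                          const NumericVector &lens,
                          const IntegerMatrix &tip_pat,
                          const NumericMatrix &U1, const NumericMatrix &U2,
                          const NumericVector &lam, const NumericVector &pi,
                          const NumericVector &rates, const NumericVector &rw,
                          std::vector<double> &out) {
  const int n_edge = edge.nrow(), n_pat = tip_pat.nrow(),
            n_cat = rates.size();
  const int root = n_tip;  // 0-based index of node n_tip + 1
  std::vector<double> P(n_edge * 16);
  std::vector<double> L(n_node * 4);
  std::fill(out.begin(), out.end(), 0.0);

  for (int c = 0; c < n_cat; ++c) {
    double Pe[4][4];
    for (int e = 0; e < n_edge; ++e) {
      edge_pmat(U1, U2, lam, rates[c] * lens[e], Pe);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) P[e * 16 + i * 4 + j] = Pe[i][j];
    }
    for (int p = 0; p < n_pat; ++p) {
      for (int n = 0; n < n_tip; ++n) {
        int m = tip_pat(p, n);
        for (int x = 0; x < 4; ++x) L[n * 4 + x] = (m >> x) & 1 ? 1.0 : 0.0;
      }
      for (int n = n_tip; n < n_node; ++n)
        for (int x = 0; x < 4; ++x) L[n * 4 + x] = 1.0;
      for (int e = 0; e < n_edge; ++e) {
        const int pa = edge(e, 0) - 1, ch = edge(e, 1) - 1;
        const double *Pp = &P[e * 16];
        for (int x = 0; x < 4; ++x) {
          double s = 0.0;
          for (int y = 0; y < 4; ++y) s += Pp[x * 4 + y] * L[ch * 4 + y];
          L[pa * 4 + x] *= s;
        }
      }
      double lik = 0.0;
      for (int x = 0; x < 4; ++x) lik += pi[x] * L[root * 4 + x];
      out[p] += rw[c] * lik;
    }
  }
  for (int p = 0; p < n_pat; ++p) out[p] = std::log(out[p]);
}

// [[Rcpp::export]]
NumericVector site_loglik_cpp(IntegerMatrix edge, int n_tip, int n_node,
                              NumericVector lens, IntegerMatrix tip_pat,
                              NumericMatrix U1, NumericMatrix U2,
                              NumericVector lam, NumericVector pi,
                              NumericVector rates, NumericVector rw) {
  std::vector<double> out(tip_pat.nrow());
  site_lik_core(edge, n_tip, n_node, lens, tip_pat, U1, U2, lam, pi, rates,
                rw, out);
  return wrap(out);
}

static double total_loglik(const IntegerMatrix &edge, int n_tip, int n_node,
                           const NumericVector &lens,
                           const IntegerMatrix &tip_pat,
                           const NumericMatrix &U1, const NumericMatrix &U2,
                           const NumericVector &lam, const NumericVector &pi,
                           const NumericVector &rates, const NumericVector &rw,
                           const NumericVector &wt,
                           std::vector<double> &scratch) {
  site_lik_core(edge, n_tip, n_node, lens, tip_pat, U1, U2, lam, pi, rates,
                rw, scratch);
  double s = 0.0;
  for (int p = 0; p < (int)scratch.size(); ++p) s += wt[p] * scratch[p];
  return s;
}

// Brent minimisation on [a, b] (Numerical-Recipes style golden section with
// parabolic steps).  Returns xmin; *fmin gets the minimum value.
template <class F>
static double brent_min(F f, double a, double b, double tol, double *fmin) {
  const double gold = 0.3819660112501051, eps = 1e-10;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx, d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + eps, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv), q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm - x >= 0 ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm ? a - x : b - x);
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmin = fx;
  return x;
}

// Reference implementation: coordinate-ascent optimisation of all branch
// lengths, each Brent evaluation recomputing the full pruning.  Kept as a
// slow-but-simple oracle for the partials-based optimiser below.
// [[Rcpp::export]]
List optimize_edges_ref_cpp(IntegerMatrix edge, int n_tip, int n_node,
                            NumericVector lens, IntegerMatrix tip_pat,
                            NumericVector wt, NumericMatrix U1,
                            NumericMatrix U2, NumericVector lam,
                            NumericVector pi, NumericVector rates,
                            NumericVector rw, int max_sweeps = 10,
                            double tol = 1e-4, double min_len = 1e-8,
                            double max_len = 20.0,
                            double brent_tol = 1e-4) {
  const int n_edge = edge.nrow();
  NumericVector cur = clone(lens);
  std::vector<double> scratch(tip_pat.nrow());
  double ll = total_loglik(edge, n_tip, n_node, cur, tip_pat, U1, U2, lam, pi,
                           rates, rw, wt, scratch);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double ll_before = ll;
    for (int e = 0; e < n_edge; ++e) {
      auto obj = [&](double t) {
        cur[e] = t;
        return -total_loglik(edge, n_tip, n_node, cur, tip_pat, U1, U2, lam,
                             pi, rates, rw, wt, scratch);
      };
      double t0 = cur[e], fmin;
      double best = brent_min(obj, min_len, max_len, brent_tol, &fmin);
      if (-fmin > ll) { cur[e] = best; ll = -fmin; }
      else cur[e] = t0;  // Brent never beat the incumbent; keep it
    }
    if (ll - ll_before < tol) break;
  }
  return List::create(_["lens"] = cur, _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// Fast branch-length optimisation with per-edge message passing.  For edge
// e = (p, c) the site likelihood is
//   L = sum_x A_e[x] * sum_y P_e(t)[x][y] * below[c][y],
// where below[c] is the pruning partial of the subtree under c and A_e folds
// in everything outside it, including the root prior.  The sweep visits
// edges in postorder, so below[c] can be rebuilt from the maintained child
// messages M_g = P_g * below[child(g)] in O(children) per node, and A_e is
// assembled by one walk from the root down to e.  A Brent evaluation then
// costs O(n_pat * n_cat * 32) regardless of tree size, and no full-tree
// refresh is ever needed.

struct MsgWorkspace {
  int n_edge, n_tip, n_node, n_pat, n_cat;
  std::vector<double> P;      // [cat][edge][16]
  std::vector<double> M;      // [cat][edge][pat][4] edge messages
  std::vector<double> below;  // [cat][node][pat][4]
  std::vector<double> A;      // [cat][pat][4] outside partial of current edge
  std::vector<std::vector<int> > children;  // node -> child edge indices
  std::vector<int> parent_edge;             // node -> incoming edge (-1 root)
  int root;
};

static inline double *mw_P(MsgWorkspace &w, int c, int e) {
  return &w.P[(c * (size_t)w.n_edge + e) * 16];
}
static inline double *mw_M(MsgWorkspace &w, int c, int e, int p) {
  return &w.M[((c * (size_t)w.n_edge + e) * w.n_pat + p) * 4];
}
static inline double *mw_below(MsgWorkspace &w, int c, int n, int p) {
  return &w.below[((c * (size_t)w.n_node + n) * w.n_pat + p) * 4];
}
static inline double *mw_A(MsgWorkspace &w, int c, int p) {
  return &w.A[(c * (size_t)w.n_pat + p) * 4];
}

static void mw_set_pmat(MsgWorkspace &w, const NumericMatrix &U1,
                        const NumericMatrix &U2, const NumericVector &lam,
                        const NumericVector &rates, int e, double t) {
  double Pe[4][4];
  for (int c = 0; c < w.n_cat; ++c) {
    edge_pmat(U1, U2, lam, rates[c] * t, Pe);
    double *dst = mw_P(w, c, e);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) dst[i * 4 + j] = Pe[i][j];
  }
}

// below[node] from its child messages (tips are set once from the masks).
static void mw_refresh_below(MsgWorkspace &w, int node) {
  for (int c = 0; c < w.n_cat; ++c)
    for (int p = 0; p < w.n_pat; ++p) {
      double *b = mw_below(w, c, node, p);
      for (int x = 0; x < 4; ++x) b[x] = 1.0;
      for (size_t k = 0; k < w.children[node].size(); ++k) {
        const double *m = mw_M(w, c, w.children[node][k], p);
        for (int x = 0; x < 4; ++x) b[x] *= m[x];
      }
    }
}

// message of edge e from the current below of its child.
static void mw_refresh_msg(MsgWorkspace &w, const IntegerMatrix &edge,
                           int e) {
  int ch = edge(e, 1) - 1;
  for (int c = 0; c < w.n_cat; ++c) {
    const double *Pp = mw_P(w, c, e);
    for (int p = 0; p < w.n_pat; ++p) {
      const double *b = mw_below(w, c, ch, p);
      double *m = mw_M(w, c, e, p);
      for (int x = 0; x < 4; ++x) {
        double s = 0.0;
        for (int y = 0; y < 4; ++y) s += Pp[x * 4 + y] * b[y];
        m[x] = s;
      }
    }
  }
}

// outside partial A_e by walking from the root down to edge e.
static void mw_compute_A(MsgWorkspace &w, const IntegerMatrix &edge,
                         const NumericVector &pi, int e) {
  std::vector<int> path;  // edges from the root-adjacent ancestor down to e
  for (int f = e; f >= 0; f = w.parent_edge[edge(f, 0) - 1])
    path.push_back(f);
  std::reverse(path.begin(), path.end());
  for (int c = 0; c < w.n_cat; ++c) {
    for (int p = 0; p < w.n_pat; ++p) {
      double *a = mw_A(w, c, p);
      for (int x = 0; x < 4; ++x) a[x] = pi[x];
    }
    for (size_t step = 0; step < path.size(); ++step) {
      int f = path[step];
      int pa = edge(f, 0) - 1;
      if (step > 0) {  // propagate through the previous path edge
        int g = path[step - 1];
        const double *Pg = mw_P(w, c, g);
        for (int p = 0; p < w.n_pat; ++p) {
          double *a = mw_A(w, c, p);
          double t[4];
          for (int x = 0; x < 4; ++x) {
            double s = 0.0;
            for (int z = 0; z < 4; ++z) s += a[z] * Pg[z * 4 + x];
            t[x] = s;
          }
          for (int x = 0; x < 4; ++x) a[x] = t[x];
        }
      }
      for (size_t k = 0; k < w.children[pa].size(); ++k) {
        int g = w.children[pa][k];
        if (g == f) continue;
        for (int p = 0; p < w.n_pat; ++p) {
          double *a = mw_A(w, c, p);
          const double *m = mw_M(w, c, g, p);
          for (int x = 0; x < 4; ++x) a[x] *= m[x];
        }
      }
    }
  }
}

// Total lnL for the current edge at candidate length t, using A and below.
static double mw_edge_loglik(MsgWorkspace &w, const IntegerMatrix &edge,
                             int e, double t, const NumericMatrix &U1,
                             const NumericMatrix &U2,
                             const NumericVector &lam,
                             const NumericVector &rates,
                             const NumericVector &rw,
                             const NumericVector &wt,
                             std::vector<double> &site) {
  int ch = edge(e, 1) - 1;
  std::fill(site.begin(), site.end(), 0.0);
  double Pe[4][4];
  for (int c = 0; c < w.n_cat; ++c) {
    edge_pmat(U1, U2, lam, rates[c] * t, Pe);
    for (int p = 0; p < w.n_pat; ++p) {
      const double *a = mw_A(w, c, p);
      const double *b = mw_below(w, c, ch, p);
      double s = 0.0;
      for (int x = 0; x < 4; ++x) {
        double m = 0.0;
        for (int y = 0; y < 4; ++y) m += Pe[x][y] * b[y];
        s += a[x] * m;
      }
      site[p] += rw[c] * s;
    }
  }
  double ll = 0.0;
  for (int p = 0; p < w.n_pat; ++p) ll += wt[p] * std::log(site[p]);
  return ll;
}

// [[Rcpp::export]]
List optimize_edges_cpp(IntegerMatrix edge, int n_tip, int n_node,
                        NumericVector lens, IntegerMatrix tip_pat,
                        NumericVector wt, NumericMatrix U1, NumericMatrix U2,
                        NumericVector lam, NumericVector pi,
                        NumericVector rates, NumericVector rw,
                        int max_sweeps = 10, double tol = 1e-4,
                        double min_len = 1e-8, double max_len = 20.0,
                        double brent_tol = 1e-4) {
  MsgWorkspace w;
  w.n_edge = edge.nrow(); w.n_tip = n_tip; w.n_node = n_node;
  w.n_pat = tip_pat.nrow(); w.n_cat = rates.size();
  w.P.resize((size_t)w.n_cat * w.n_edge * 16);
  w.M.resize((size_t)w.n_cat * w.n_edge * w.n_pat * 4);
  w.below.resize((size_t)w.n_cat * w.n_node * w.n_pat * 4);
  w.A.resize((size_t)w.n_cat * w.n_pat * 4);
  w.children.assign(n_node, std::vector<int>());
  w.parent_edge.assign(n_node, -1);
  for (int e = 0; e < w.n_edge; ++e) {
    w.children[edge(e, 0) - 1].push_back(e);
    w.parent_edge[edge(e, 1) - 1] = e;
  }
  // tip below partials from the ambiguity masks, once
  for (int c = 0; c < w.n_cat; ++c)
    for (int p = 0; p < w.n_pat; ++p)
      for (int n = 0; n < n_tip; ++n) {
        int m = tip_pat(p, n);
        double *b = mw_below(w, c, n, p);
        for (int x = 0; x < 4; ++x) b[x] = (m >> x) & 1 ? 1.0 : 0.0;
      }
  NumericVector cur = clone(lens);
  for (int e = 0; e < w.n_edge; ++e)
    mw_set_pmat(w, U1, U2, lam, rates, e, cur[e]);
  // initial postorder pass: internal below partials and all messages
  for (int e = 0; e < w.n_edge; ++e) {
    int ch = edge(e, 1) - 1;
    if (ch >= n_tip) mw_refresh_below(w, ch);
    mw_refresh_msg(w, edge, e);
  }
  std::vector<double> site(w.n_pat), scratch(w.n_pat);
  double ll = total_loglik(edge, n_tip, n_node, cur, tip_pat, U1, U2, lam,
                           pi, rates, rw, wt, scratch);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double ll_before = ll;
    for (int e = 0; e < w.n_edge; ++e) {
      int ch = edge(e, 1) - 1;
      if (ch >= n_tip) mw_refresh_below(w, ch);  // subtree done this sweep
      mw_compute_A(w, edge, pi, e);
      auto obj = [&](double t) {
        return -mw_edge_loglik(w, edge, e, t, U1, U2, lam, rates, rw, wt,
                               site);
      };
      double fmin;
      double best = brent_min(obj, min_len, max_len, brent_tol, &fmin);
      if (-fmin > ll) {
        cur[e] = best;
        ll = -fmin;
        mw_set_pmat(w, U1, U2, lam, rates, e, cur[e]);
      }
      mw_refresh_msg(w, edge, e);  // keep M_e in step with below[ch]
    }
    if (ll - ll_before < tol) break;
  }
  // consistency: recompute the total with plain pruning
  site_lik_core(edge, n_tip, n_node, cur, tip_pat, U1, U2, lam, pi, rates,
                rw, scratch);
  double ll_check = 0.0;
  for (int p = 0; p < w.n_pat; ++p) ll_check += wt[p] * scratch[p];
  return List::create(_["lens"] = cur, _["loglik"] = ll_check);
}
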