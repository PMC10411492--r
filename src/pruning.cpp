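// GTR+Gamma pruning likelihood and fixed-topology branch-length
// optimization. Trees arrive as ape-style edge matrices in postorder;
// tip rows of `codes` follow node ids 1..ntip. States 0..3 = A,C,G,T,
// 4 = fully ambiguous (gap or N). Underflow is handled by per-node,
// per-pattern rescaling with accumulated log scale factors.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Brent's derivative-free minimizer on [ax, bx] (golden section with
// parabolic interpolation), tolerance on the abscissa.
template <typename F>
double brent_min(double ax, double bx, F f, double tol) {
  const double gold = 0.3819660112501051;
  const double eps = std::sqrt(2.220446049250313e-16);
  double a = ax, b = bx;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; iter++) {
    double xm = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

struct Engine {
  int ntip, nn, npat, k, nedge, root;
  std::vector<std::vector<int>> kids;   // children node ids per node (1-based)
  std::vector<int> par;                 // parent node id per node (0 = none)
  std::vector<int> eidx;                // edge row of the edge above each node
  std::vector<int> rows_child;          // edge rows: child node per row
  std::vector<int> rows_par;
  std::vector<double> el;               // current branch lengths per edge row
  std::vector<int> codes;               // ntip x npat, row-major by tip
  std::vector<double> w;                // pattern weights
  double pi[4];
  double U[16], Ui[16], lam[4];
  std::vector<double> rates;            // k category rates, mean 1
  double min_bl, max_bl;

  // workspaces: partials indexed [node][cat][state][pat]
  std::vector<double> D, A;             // down partials, outside partials
  std::vector<double> Ds, As;           // per-node per-pattern log scales
  std::vector<double> Out, OutS;        // edge-local outside buffer (one node)
  std::vector<double> P;                // k transition matrices (k*16)
  std::vector<double> msgbuf, accbuf, mxbuf;  // preallocated scratch
  std::vector<int> lastrow;             // last edge row per parent node

  void ensure_up_buffers() {            // outside partials only for sweeps
    size_t sz = (size_t)nn * k * 4 * npat;
    if (A.size() != sz) {
      A.resize(sz);
      As.resize((size_t)nn * npat);
      Out.resize((size_t)k * 4 * npat);
      OutS.resize(npat);
    }
  }

  inline double *dpt(std::vector<double> &buf, int node, int cat) {
    return &buf[((size_t)(node - 1) * k + cat) * 4 * npat];
  }
  inline double *spt(std::vector<double> &buf, int node) {
    return &buf[(size_t)(node - 1) * npat];
  }

  void pmat(double t, double *Pm) const {
    double e[4];
    for (int i = 0; i < 4; i++) e[i] = std::exp(lam[i] * t);
    for (int x = 0; x < 4; x++)
      for (int y = 0; y < 4; y++) {
        double s = 0;
        for (int i = 0; i < 4; i++) s += U[x * 4 + i] * e[i] * Ui[i * 4 + y];
        Pm[x * 4 + y] = s > 1e-300 ? s : 1e-300;
      }
  }

  void pmats(double t) {
    for (int c = 0; c < k; c++) pmat(t * rates[c], &P[c * 16]);
  }

  // message of child node `c` to its parent, for one category:
  // msg[x][pat] = sum_y P[x][y] * partial_c[y][pat]
  void child_message(int c, const double *Pm, int cat, double *msg) {
    if (c <= ntip) {
      const int *st = &codes[(size_t)(c - 1) * npat];
      for (int p = 0; p < npat; p++) {
        int s = st[p];
        if (s < 4)
          for (int x = 0; x < 4; x++) msg[x * npat + p] = Pm[x * 4 + s];
        else
          for (int x = 0; x < 4; x++) msg[x * npat + p] = 1.0;
      }
    } else {
      const double *d = dpt(D, c, cat);
      for (int x = 0; x < 4; x++)
        for (int p = 0; p < npat; p++) {
          double s = 0;
          for (int y = 0; y < 4; y++) s += Pm[x * 4 + y] * d[y * npat + p];
          msg[x * npat + p] = s;
        }
    }
  }

  // joint rescaling of a node's partials across categories; the divide
  // pass is skipped while magnitudes stay far from the underflow range
  void rescale(std::vector<double> &buf, std::vector<double> &sbuf, int node) {
    double *sc = spt(sbuf, node);
    std::vector<double> &mx = mxbuf;
    std::fill(mx.begin(), mx.end(), 0.0);
    for (int c = 0; c < k; c++) {
      double *d = dpt(buf, node, c);
      for (int x = 0; x < 4; x++)
        for (int p = 0; p < npat; p++)
          if (d[x * npat + p] > mx[p]) mx[p] = d[x * npat + p];
    }
    bool need = false;
    for (int p = 0; p < npat; p++)
      if (!(mx[p] > 1e-80 && mx[p] < 1e80)) { need = true; break; }
    if (!need) return;
    for (int p = 0; p < npat; p++) {
      if (mx[p] <= 0) mx[p] = 1e-300;
      sc[p] += std::log(mx[p]);
    }
    for (int c = 0; c < k; c++) {
      double *d = dpt(buf, node, c);
      for (int x = 0; x < 4; x++)
        for (int p = 0; p < npat; p++) d[x * npat + p] /= mx[p];
    }
  }

  void compute_down() {
    std::fill(D.begin(), D.end(), 1.0);
    std::fill(Ds.begin(), Ds.end(), 0.0);
    std::vector<double> &msg = msgbuf;
    for (int r = 0; r < nedge; r++) {
      int p = rows_par[r], c = rows_child[r];
      pmats(el[r]);
      for (int cat = 0; cat < k; cat++) {
        child_message(c, &P[cat * 16], cat, msg.data());
        double *d = dpt(D, p, cat);
        for (size_t i = 0; i < 4 * (size_t)npat; i++) d[i] *= msg[i];
      }
      if (c > ntip) {
        double *sp = spt(Ds, p), *sch = spt(Ds, c);
        for (int pp = 0; pp < npat; pp++) sp[pp] += sch[pp];
      }
      if (r == lastrow[p]) rescale(D, Ds, p);
    }
  }

  // pattern log-likelihoods at the root from the down partials
  double root_loglik(std::vector<double> *patll = nullptr) {
    double total = 0;
    const double *sc = spt(Ds, root);
    for (int p = 0; p < npat; p++) {
      double s = 0;
      for (int c = 0; c < k; c++) {
        const double *d = dpt(D, root, c);
        for (int x = 0; x < 4; x++) s += pi[x] * d[x * npat + p];
      }
      double ll = std::log(s / k) + sc[p];
      if (patll) (*patll)[p] = ll;
      total += w[p] * ll;
    }
    return total;
  }

  double loglik(std::vector<double> *patll = nullptr) {
    compute_down();
    return root_loglik(patll);
  }

  // edge-local log-likelihood for the edge above node v, at length t,
  // given Out/OutS (outside partials at the parent end) and the down
  // partials of v; scale constants independent of t are included so the
  // value is the exact lnL.
  double edge_loglik(int v, double t) {
    pmats(t);
    std::vector<double> &msg = msgbuf;
    std::vector<double> &acc = accbuf;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int cat = 0; cat < k; cat++) {
      child_message(v, &P[cat * 16], cat, msg.data());
      const double *o = &Out[(size_t)cat * 4 * npat];
      for (int x = 0; x < 4; x++)
        for (int p = 0; p < npat; p++)
          acc[p] += o[x * npat + p] * msg[x * npat + p];
    }
    double total = 0;
    const double *vsc = (v > ntip) ? spt(Ds, v) : nullptr;
    for (int p = 0; p < npat; p++) {
      double add = OutS[p] + (vsc ? vsc[p] : 0.0);
      total += w[p] * (std::log(acc[p] / k > 0 ? acc[p] / k : 1e-300) + add);
    }
    return total;
  }

  // Fill Out/OutS for child v of node p using the current branch lengths
  // of v's siblings and the outside partials A at p.
  void fill_out(int p, int v) {
    std::fill(OutS.begin(), OutS.end(), 0.0);
    const double *asc = spt(As, p);
    for (int pp = 0; pp < npat; pp++) OutS[pp] = asc[pp];
    for (int cat = 0; cat < k; cat++) {
      const double *a = dpt(A, p, cat);
      double *o = &Out[(size_t)cat * 4 * npat];
      for (size_t i = 0; i < 4 * (size_t)npat; i++) o[i] = a[i];
    }
    std::vector<double> &msg = msgbuf;
    for (int s : kids[p]) {
      if (s == v) continue;
      pmats(el[eidx[s]]);
      for (int cat = 0; cat < k; cat++) {
        child_message(s, &P[cat * 16], cat, msg.data());
        double *o = &Out[(size_t)cat * 4 * npat];
        for (size_t i = 0; i < 4 * (size_t)npat; i++) o[i] *= msg[i];
      }
      if (s > ntip) {
        const double *ssc = spt(Ds, s);
        for (int pp = 0; pp < npat; pp++) OutS[pp] += ssc[pp];
      }
    }
    // rescale Out across categories
    std::vector<double> &mx = mxbuf;
    std::fill(mx.begin(), mx.end(), 0.0);
    for (int cat = 0; cat < k; cat++) {
      const double *o = &Out[(size_t)cat * 4 * npat];
      for (size_t i = 0; i < 4 * (size_t)npat; i++) {
        int p2 = (int)(i % npat);
        if (o[i] > mx[p2]) mx[p2] = o[i];
      }
    }
    for (int pp = 0; pp < npat; pp++) {
      if (mx[pp] <= 0) mx[pp] = 1e-300;
      OutS[pp] += std::log(mx[pp]);
    }
    for (int cat = 0; cat < k; cat++) {
      double *o = &Out[(size_t)cat * 4 * npat];
      for (size_t i = 0; i < 4 * (size_t)npat; i++) o[i] /= mx[i % npat];
    }
  }

  // Anc at v: propagate the current Out through the (possibly updated)
  // edge above v, so v's own children can be optimized next
  void push_anc(int v, int r, std::vector<int> &stack) {
    pmats(el[r]);
    double *vs = spt(As, v);
    for (int pp = 0; pp < npat; pp++) vs[pp] = OutS[pp];
    for (int cat = 0; cat < k; cat++) {
      const double *Pm = &P[cat * 16];
      const double *o = &Out[(size_t)cat * 4 * npat];
      double *a = dpt(A, v, cat);
      for (int x = 0; x < 4; x++)
        for (int pp = 0; pp < npat; pp++) {
          double s = 0;
          for (int xp = 0; xp < 4; xp++)
            s += o[xp * npat + pp] * Pm[xp * 4 + x];
          a[x * npat + pp] = s;
        }
    }
    rescale(A, As, v);
    stack.push_back(v);
  }

  // Pre-order sweep: optimize each branch with the subtree partials D
  // (valid: only lengths above a node change before its edge is visited)
  // and outside partials A maintained top-down with updated lengths.
  void sweep() {
    ensure_up_buffers();
    // A at root = pi, no scale
    std::fill(As.begin(), As.end(), 0.0);
    for (int cat = 0; cat < k; cat++) {
      double *a = dpt(A, root, cat);
      for (int x = 0; x < 4; x++)
        for (int p = 0; p < npat; p++) a[x * npat + p] = pi[x];
    }
    std::vector<int> stack = {root};
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      for (int v : kids[p]) {
        fill_out(p, v);
        int r = eidx[v];
        double t0 = el[r], f0 = edge_loglik(v, t0);
        // edges stuck at the floor: one cheap probe instead of a full
        // bracketed search (the lnL there is flat at the ~1e-4 scale)
        if (t0 <= 16.0 * min_bl) {
          double f_lo = edge_loglik(v, min_bl);
          double f_probe = edge_loglik(v, 1e-4);
          if (f_lo >= f_probe) {
            if (f_lo > f0) el[r] = min_bl;
            if (v > ntip) push_anc(v, r, stack);
            continue;
          }
        }
        // bracket warm around the current length; widen to the full range
        // if the optimum presses against the warm bracket
        double lo = std::max(min_bl, t0 / 8.0);
        double hi = std::min(max_bl, std::max(t0 * 8.0, 0.05));
        double t1 = brent_min(lo, hi,
                              [&](double t) { return -edge_loglik(v, t); },
                              1e-6);
        if (t1 < lo * 1.2 && lo > min_bl * 1.5) {
          t1 = brent_min(min_bl, t1 * 1.2,
                         [&](double t) { return -edge_loglik(v, t); }, 1e-6);
        } else if (t1 > hi / 1.2 && hi < max_bl / 1.5) {
          t1 = brent_min(t1 / 1.2, max_bl,
                         [&](double t) { return -edge_loglik(v, t); }, 1e-6);
        }
        double f1 = edge_loglik(v, t1);
        if (f1 > f0) el[r] = t1;  // keep the better point: lnL never drops
        if (v > ntip) push_anc(v, r, stack);
      }
    }
  }
};

void set_model(Engine &e, const NumericVector &pi, const NumericMatrix &U,
               const NumericMatrix &Ui, const NumericVector &lam,
               const NumericVector &rates) {
  int k = rates.size();
  for (int i = 0; i < 4; i++) e.pi[i] = pi[i];
  for (int x = 0; x < 4; x++)
    for (int y = 0; y < 4; y++) {
      e.U[x * 4 + y] = U(x, y);
      e.Ui[x * 4 + y] = Ui(x, y);
    }
  for (int i = 0; i < 4; i++) e.lam[i] = lam[i];
  e.rates.assign(rates.begin(), rates.end());
  if (k != e.k) {
    e.k = k;
    e.D.resize((size_t)e.nn * k * 4 * e.npat);
    e.P.resize((size_t)k * 16);
    e.A.clear();  // reallocated on demand with the new k
    e.msgbuf.resize(4 * (size_t)e.npat);
  }
}

Engine *build_engine(const IntegerMatrix &edge, const NumericVector &edge_len,
                     int ntip, const IntegerMatrix &codes,
                     const NumericVector &weights, int k) {
  Engine *ep = new Engine();
  Engine &e = *ep;
  e.ntip = ntip;
  e.nedge = edge.nrow();
  e.npat = codes.ncol();
  e.k = k;
  e.min_bl = 1e-8;
  e.max_bl = 10.0;
  int nn = ntip;
  for (int r = 0; r < e.nedge; r++)
    nn = std::max(nn, std::max(edge(r, 0), edge(r, 1)));
  e.nn = nn;
  e.kids.assign(nn + 1, {});
  e.par.assign(nn + 1, 0);
  e.eidx.assign(nn + 1, -1);
  e.rows_par.resize(e.nedge);
  e.rows_child.resize(e.nedge);
  e.el.resize(e.nedge);
  e.lastrow.assign(nn + 1, -1);
  for (int r = 0; r < e.nedge; r++) {
    int p = edge(r, 0), c = edge(r, 1);
    e.rows_par[r] = p;
    e.rows_child[r] = c;
    e.kids[p].push_back(c);
    e.par[c] = p;
    e.eidx[c] = r;
    e.el[r] = edge_len[r] < 0 ? 0 : edge_len[r];
    e.lastrow[p] = r;
  }
  e.root = -1;
  for (int v = ntip + 1; v <= nn; v++)
    if (e.par[v] == 0) e.root = v;
  if (e.root < 0) { delete ep; stop("bad edge matrix: no root found"); }
  e.codes.resize((size_t)ntip * e.npat);
  for (int i = 0; i < ntip; i++)
    for (int p = 0; p < e.npat; p++) e.codes[(size_t)i * e.npat + p] = codes(i, p);
  e.w.assign(weights.begin(), weights.end());
  e.D.resize((size_t)nn * e.k * 4 * e.npat);
  e.Ds.resize((size_t)nn * e.npat);
  e.P.resize((size_t)e.k * 16);
  e.msgbuf.resize(4 * (size_t)e.npat);
  e.accbuf.resize(e.npat);
  e.mxbuf.resize(e.npat);
  return ep;
}

Engine make_engine(const IntegerMatrix &edge, const NumericVector &edge_len,
                   int ntip, const IntegerMatrix &codes,
                   const NumericVector &weights, const NumericVector &pi,
                   const NumericMatrix &U, const NumericMatrix &Ui,
                   const NumericVector &lam, const NumericVector &rates) {
  Engine *ep = build_engine(edge, edge_len, ntip, codes, weights,
                            rates.size());
  Engine e = *ep;
  delete ep;
  set_model(e, pi, U, Ui, lam, rates);
  return e;
}

// diagnostic: edge-local lnL at current lengths for every edge; each
// value must equal the global lnL
std::vector<double> edge_lnl_all(Engine &e) {
  e.ensure_up_buffers();
  e.compute_down();
  std::vector<double> out(e.nedge, NA_REAL);
  std::fill(e.As.begin(), e.As.end(), 0.0);
  for (int cat = 0; cat < e.k; cat++) {
    double *a = e.dpt(e.A, e.root, cat);
    for (int x = 0; x < 4; x++)
      for (int p = 0; p < e.npat; p++) a[x * e.npat + p] = e.pi[x];
  }
  std::vector<int> stack = {e.root};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    for (int v : e.kids[p]) {
      e.fill_out(p, v);
      int r = e.eidx[v];
      out[r] = e.edge_loglik(v, e.el[r]);
      if (v > e.ntip) {
        e.pmats(e.el[r]);
        double *vs = e.spt(e.As, v);
        for (int pp = 0; pp < e.npat; pp++) vs[pp] = e.OutS[pp];
        for (int cat = 0; cat < e.k; cat++) {
          const double *Pm = &e.P[cat * 16];
          const double *o = &e.Out[(size_t)cat * 4 * e.npat];
          double *a = e.dpt(e.A, v, cat);
          for (int x = 0; x < 4; x++)
            for (int pp = 0; pp < e.npat; pp++) {
              double s = 0;
              for (int xp = 0; xp < 4; xp++)
                s += o[xp * e.npat + pp] * Pm[xp * 4 + x];
              a[x * e.npat + pp] = s;
            }
        }
        e.rescale(e.A, e.As, v);
        stack.push_back(v);
      }
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_edge_lnl_check")]]
NumericVector cpp_edge_lnl_check(IntegerMatrix edge, NumericVector edge_len,
                                 int ntip, IntegerMatrix codes,
                                 NumericVector weights, NumericVector pi,
                                 NumericMatrix U, NumericMatrix Ui,
                                 NumericVector lam, NumericVector rates) {
  Engine e = make_engine(edge, edge_len, ntip, codes, weights, pi, U, Ui,
                         lam, rates);
  std::vector<double> v = edge_lnl_all(e);
  return NumericVector(v.begin(), v.end());
}

// [[Rcpp::export(name = ".cpp_make_engine")]]
SEXP cpp_make_engine(IntegerMatrix edge, NumericVector edge_len, int ntip,
                     IntegerMatrix codes, NumericVector weights, int k) {
  XPtr<Engine> p(build_engine(edge, edge_len, ntip, codes, weights, k), true);
  return p;
}

// [[Rcpp::export(name = ".cpp_engine_loglik")]]
double cpp_engine_loglik(SEXP eng, NumericVector pi, NumericMatrix U,
                         NumericMatrix Ui, NumericVector lam,
                         NumericVector rates) {
  XPtr<Engine> p(eng);
  set_model(*p, pi, U, Ui, lam, rates);
  return p->loglik();
}

// [[Rcpp::export(name = ".cpp_tree_loglik")]]
List cpp_tree_loglik(IntegerMatrix edge, NumericVector edge_len, int ntip,
                     IntegerMatrix codes, NumericVector weights,
                     NumericVector pi, NumericMatrix U, NumericMatrix Ui,
                     NumericVector lam, NumericVector rates) {
  Engine e = make_engine(edge, edge_len, ntip, codes, weights, pi, U, Ui,
                         lam, rates);
  std::vector<double> patll(e.npat);
  double total = e.loglik(&patll);
  return List::create(_["loglik"] = total,
                      _["pattern_loglik"] = NumericVector(patll.begin(), patll.end()));
}

// [[Rcpp::export(name = ".cpp_optimize_bl")]]
List cpp_optimize_bl(IntegerMatrix edge, NumericVector edge_len, int ntip,
                     IntegerMatrix codes, NumericVector weights,
                     NumericVector pi, NumericMatrix U, NumericMatrix Ui,
                     NumericVector lam, NumericVector rates,
                     double tol = 1e-4, int max_sweeps = 20) {
  Engine e = make_engine(edge, edge_len, ntip, codes, weights, pi, U, Ui,
                         lam, rates);
  for (int r = 0; r < e.nedge; r++)
    if (e.el[r] < e.min_bl) e.el[r] = e.min_bl;
  double prev = e.loglik();
  int sweeps = 0;
  double cur = prev;
  while (sweeps < max_sweeps) {
    std::vector<double> saved = e.el;
    e.sweep();
    cur = e.loglik();
    sweeps++;
    if (!std::isfinite(cur)) stop("numerical error: non-finite likelihood");
    if (cur < prev) {  // stale outside partials can misguide a move: revert
      e.el = saved;
      cur = prev;
      break;
    }
    if (cur - prev < tol) break;
    prev = cur;
  }
  std::vector<double> patll(e.npat);
  double total = e.loglik(&patll);
  return List::create(_["loglik"] = total,
                      _["edge_length"] = NumericVector(e.el.begin(), e.el.end()),
                      _["sweeps"] = sweeps,
                      _["pattern_loglik"] = NumericVector(patll.begin(), patll.end()));
}
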