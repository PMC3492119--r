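#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Minimum-cost flip-set dynamic program over a duplication forest.
//
// A(u,v,s) = minimum cost of flip edges placed between the subtree of u and
// the subtree of v so that, given the parity state s of flips already placed
// at or above (u,v), every Present leaf pair across the two subtrees matches
// the target adjacency. The recurrence either splits one (internal) side, or
// places a flip at (u,v) — paying the add cost when the pair's parity is
// even, the loss cost when odd, plus any branch-length penalty — and then
// splits. Splitting after a flip forbids a second flip on the same pair, so
// no 1- or 2-blocking loop can be produced. S(u) adds sibling-pair terms
// over the subtree below u.
//
// States: undirected 2 (parity of the pair); directed 4 (bit0 = parity of
// a->b, bit1 = parity of b->a, with (a,b) the canonical min/max-index roles).
// All indices 0-based; leaves have left = right = -1.

static const double INF = std::numeric_limits<double>::infinity();

struct DP {
  int n, ns;
  bool directed, selfloops;
  const IntegerVector &left, &right;
  const LogicalVector &present;
  const IntegerMatrix &adj;
  const NumericMatrix &pen;
  const LogicalMatrix &forbid;
  double cadd, closs;
  std::vector<double> A;
  mutable std::vector<double> Smemo;

  DP(int n_, bool dir, bool sloop, const IntegerVector &l,
     const IntegerVector &r, const LogicalVector &pres,
     const IntegerMatrix &adj_, const NumericMatrix &pen_,
     const LogicalMatrix &forb, double ca, double cl)
    : n(n_), ns(dir ? 4 : 2), directed(dir), selfloops(sloop), left(l),
      right(r), present(pres), adj(adj_), pen(pen_), forbid(forb),
      cadd(ca), closs(cl), A(std::size_t(n_) * n_ * (dir ? 4 : 2), 0.0),
      Smemo(std::size_t(n_) * 2, NA_REAL) {}

  inline bool leaf(int u) const { return left[u] < 0; }
  inline double c(int p) const { return p ? closs : cadd; }

  // canonical storage: roles (a,b) with a < b; state bits refer to (a,b)
  inline double getA(int u, int v, int s) const {
    if (u == v) Rcpp::stop("internal error: self pair in A");
    if (u < v) return A[(std::size_t(s) * n + u) * n + v];
    int sw = directed ? ((s & 1) << 1) | ((s >> 1) & 1) : s;
    return A[(std::size_t(sw) * n + v) * n + u];
  }
  inline void setA(int a, int b, int s, double val) {
    A[(std::size_t(s) * n + a) * n + b] = val;
  }

  // ---- option enumeration (a < b canonical) ----
  struct Opt {
    double cost;     // local cost of flips taken at (a,b)
    int e;           // flip bits: undirected 0/1; directed bit0 a->b, bit1 b->a
    int split;       // 0 split a, 1 split b
    int s2;          // child state
  };

  // value of option o at (a,b): local cost + child terms under state s2.
  // Role order (a-side first) is preserved so state bits stay aligned.
  inline double optValue(int a, int b, const Opt &o) const {
    if (o.split == 0)
      return o.cost + getA(left[a], b, o.s2) + getA(right[a], b, o.s2);
    return o.cost + getA(a, left[b], o.s2) + getA(a, right[b], o.s2);
  }

  void options(int a, int b, int s, std::vector<Opt> &out) const {
    out.clear();
    int emax = directed ? 3 : 1;
    for (int e = 0; e <= emax; ++e) {
      double ce = 0.0;
      bool ok = true;
      if (directed) {
        if (e & 1) { if (forbid(a, b)) ok = false;
                     else ce += c(s & 1) + pen(a, b); }
        if (e & 2) { if (forbid(b, a)) ok = false;
                     else ce += c((s >> 1) & 1) + pen(a, b); }
      } else if (e == 1) {
        if (forbid(a, b) || forbid(b, a)) ok = false;
        else ce += c(s) + pen(a, b);
      }
      if (!ok) continue;
      int s2 = s ^ e;
      if (!leaf(a)) out.push_back({ce, e, 0, s2});
      if (!leaf(b)) out.push_back({ce, e, 1, s2});
    }
  }

  // base cost at a leaf-leaf pair (a < b), also used by backtracking
  double baseCost(int a, int b, int s) const {
    if (!present[a] || !present[b]) return 0.0;   // Absent lineages: no constraint
    if (directed) {
      double tot = 0.0;
      int fab = adj(a, b) ^ (s & 1), fba = adj(b, a) ^ ((s >> 1) & 1);
      if (fab) tot += forbid(a, b) ? INF : c(s & 1) + pen(a, b);
      if (fba) tot += forbid(b, a) ? INF : c((s >> 1) & 1) + pen(a, b);
      return tot;
    }
    int f = adj(a, b) ^ s;
    if (!f) return 0.0;
    return (forbid(a, b) || forbid(b, a)) ? INF : c(s) + pen(a, b);
  }

  // comparable pairs (one an ancestor of the other) never arise from the
  // top-level recursion over incomparable pairs and are skipped
  void fill(const IntegerVector &post, const IntegerVector &ein,
            const IntegerVector &eout, const IntegerVector &tree) {
    std::vector<Opt> opts;
    int np = post.size();
    for (int i = 0; i < np; ++i) {
      for (int j = 0; j < i; ++j) {
        int x = post[i], y = post[j];
        if (tree[x] == tree[y] &&
            ((ein[x] <= ein[y] && eout[x] >= eout[y]) ||
             (ein[y] <= ein[x] && eout[y] >= eout[x])))
          continue;
        int a = std::min(x, y), b = std::max(x, y);
        for (int s = 0; s < ns; ++s) {
          double best;
          if (leaf(a) && leaf(b)) {
            best = baseCost(a, b, s);
          } else {
            options(a, b, s, opts);
            best = INF;
            for (const Opt &o : opts) {
              double val = optValue(a, b, o);
              if (val < best) best = val;
            }
          }
          setA(a, b, s, best);
        }
      }
    }
  }

  // S(u, p): subtree term. In the self-loop variant a flip at (u, u) may be
  // paid to toggle every interaction (self-loops included) among the
  // descendants of u; its leaf base pays for a required self-loop.
  double S(int u, int p) const {
    double &memo = Smemo[std::size_t(p) * n + u];
    if (!ISNA(memo)) return memo;
    double val;
    if (leaf(u)) {
      val = (selfloops && present[u] && (adj(u, u) ^ p)) ? c(p) : 0.0;
    } else {
      val = S(left[u], p) + S(right[u], p) + getA(left[u], right[u], p);
      if (selfloops) {
        double alt = c(p) + pen(u, u) + S(left[u], p ^ 1) + S(right[u], p ^ 1)
                   + getA(left[u], right[u], p ^ 1);
        if (alt < val) val = alt;
      }
    }
    memo = val;
    return val;
  }

  // ---- backtracking ----
  struct Flip { int a, b, dir, parity; double cost; };

  void backtrackPair(int u, int v, int s, std::vector<Flip> &flips) const {
    int a = std::min(u, v), b = std::max(u, v);
    if (u > v && directed) s = ((s & 1) << 1) | ((s >> 1) & 1);
    if (leaf(a) && leaf(b)) {
      if (!present[a] || !present[b]) return;
      if (directed) {
        if (adj(a, b) ^ (s & 1))
          flips.push_back({a, b, 1, s & 1, c(s & 1) + pen(a, b)});
        if (adj(b, a) ^ ((s >> 1) & 1))
          flips.push_back({b, a, 1, (s >> 1) & 1, c((s >> 1) & 1) + pen(a, b)});
      } else if (adj(a, b) ^ s) {
        flips.push_back({a, b, 0, s, c(s) + pen(a, b)});
      }
      return;
    }
    std::vector<Opt> opts;
    options(a, b, s, opts);
    double best = getA(a, b, s);
    if (!std::isfinite(best)) Rcpp::stop("no feasible flip set (over-constrained)");
    for (const Opt &o : opts) {
      if (optValue(a, b, o) <= best + 1e-9) {
        if (o.e) {
          if (directed) {
            if (o.e & 1) flips.push_back({a, b, 1, s & 1, c(s & 1) + pen(a, b)});
            if (o.e & 2) flips.push_back({b, a, 1, (s >> 1) & 1,
                                          c((s >> 1) & 1) + pen(a, b)});
          } else {
            flips.push_back({a, b, 0, s, c(s) + pen(a, b)});
          }
        }
        if (o.split == 0) {
          backtrackPair(left[a], b, o.s2, flips);
          backtrackPair(right[a], b, o.s2, flips);
        } else {
          backtrackPair(a, left[b], o.s2, flips);
          backtrackPair(a, right[b], o.s2, flips);
        }
        return;
      }
    }
    Rcpp::stop("internal error: backtracking found no optimal option");
  }

  void backtrackS(int u, int p, std::vector<Flip> &flips) const {
    if (leaf(u)) {
      if (selfloops && present[u] && (adj(u, u) ^ p))
        flips.push_back({u, u, 0, p, c(p)});
      return;
    }
    int pc = p;
    if (selfloops) {
      double plain = S(left[u], p) + S(right[u], p) + getA(left[u], right[u], p);
      if (plain > S(u, p) + 1e-9) {          // self-flip branch was chosen
        flips.push_back({u, u, 0, p, c(p) + pen(u, u)});
        pc = p ^ 1;
      }
    }
    backtrackS(left[u], pc, flips);
    backtrackS(right[u], pc, flips);
    backtrackPair(left[u], right[u], pc, flips);
  }
};

// [[Rcpp::export]]
List dp_flips_cpp(IntegerVector left, IntegerVector right,
                  LogicalVector present, IntegerVector post,
                  IntegerVector roots, IntegerMatrix adj, bool directed,
                  bool selfloops, double cadd, double closs,
                  NumericMatrix pen, LogicalMatrix forbid,
                  IntegerVector ein, IntegerVector eout, IntegerVector tree,
                  bool backtrack) {
  int n = left.size();
  DP dp(n, directed, selfloops, left, right, present, adj, pen, forbid,
        cadd, closs);
  dp.fill(post, ein, eout, tree);

  NumericVector Sv(roots.size()), Sv1(roots.size());
  double total = 0.0;
  for (int i = 0; i < roots.size(); ++i) {
    Sv[i] = dp.S(roots[i], 0);
    Sv1[i] = selfloops ? dp.S(roots[i], 1) : NA_REAL;
    total += Sv[i];
  }
  for (int i = 0; i < roots.size(); ++i)
    for (int j = i + 1; j < roots.size(); ++j)
      total += dp.getA(roots[i], roots[j], 0);

  List out = List::create(_["total"] = total, _["S_roots"] = Sv,
                          _["S_roots_odd"] = Sv1);

  // full (n, n, ns) array view of A for ancestor inference and inspection
  NumericVector Aarr(std::size_t(n) * n * dp.ns, NA_REAL);
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      for (int s = 0; s < dp.ns; ++s) {
        double v = dp.A[(std::size_t(s) * n + a) * n + b];
        Aarr[std::size_t(s) * n * n + std::size_t(b) * n + a] = v;   // [a, b, s]
        int sw = directed ? ((s & 1) << 1) | ((s >> 1) & 1) : s;
        Aarr[std::size_t(sw) * n * n + std::size_t(a) * n + b] = v;  // [b, a, sw]
      }
  Aarr.attr("dim") = IntegerVector::create(n, n, dp.ns);
  out["A"] = Aarr;

  if (backtrack) {
    std::vector<DP::Flip> flips;
    for (int i = 0; i < roots.size(); ++i)
      dp.backtrackS(roots[i], 0, flips);
    for (int i = 0; i < roots.size(); ++i)
      for (int j = i + 1; j < roots.size(); ++j)
        dp.backtrackPair(roots[i], roots[j], 0, flips);
    int m = flips.size();
    IntegerVector fa(m), fb(m), fparity(m);
    NumericVector fcost(m);
    for (int k = 0; k < m; ++k) {
      fa[k] = flips[k].a + 1; fb[k] = flips[k].b + 1;
      fparity[k] = flips[k].parity; fcost[k] = flips[k].cost;
    }
    out["flip_a"] = fa; out["flip_b"] = fb;
    out["flip_parity"] = fparity; out["flip_cost"] = fcost;
  }
  return out;
}
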