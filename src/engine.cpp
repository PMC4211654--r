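// R interface to the symbolic kernel.
#include <Rcpp.h>
#include <cmath>
#include "groebner.h"

using namespace Rcpp;
using namespace icb;

// ---------- serialization ----------

static PolyQ r_to_pq(List p) {
  IntegerMatrix exp = p["exp"];
  CharacterVector cs = p["c"];
  PolyQ q; q.nv = exp.ncol();
  for (int i = 0; i < exp.nrow(); ++i) {
    Expo e(q.nv);
    for (int j = 0; j < q.nv; ++j) {
      int v = exp(i, j);
      if (v < 0) stop("negative exponent");
      e[j] = (uint16_t)v;
    }
    q.add_term(e, rat_from_str(as<std::string>(cs[i])));
  }
  return q;
}

static List pq_to_r(const PolyQ& q) {
  int n = (int)q.t.size();
  IntegerMatrix exp(n, q.nv);
  CharacterVector cs(n);
  int i = 0;
  for (auto& kv : q.t) {
    for (int j = 0; j < q.nv; ++j) exp(i, j) = kv.first[j];
    cs[i] = rat_to_str(kv.second);
    ++i;
  }
  return List::create(_["exp"] = exp, _["c"] = cs);
}

static List rf_to_r(const RF& f) {
  return List::create(_["num"] = pq_to_r(f.num), _["den"] = pq_to_r(f.den));
}
static RF r_to_rf(List f) {
  RF r;
  r.num = r_to_pq(f["num"]);
  r.den = r_to_pq(f["den"]);
  if (r.den.is0()) stop("rational function with zero denominator");
  return r;
}

static Order r_to_order(List blocks) {
  Order o;
  for (int i = 0; i < blocks.size(); ++i) {
    IntegerVector b = blocks[i];
    std::vector<int> blk;
    for (int j = 0; j < b.size(); ++j) blk.push_back(b[j] - 1);
    o.blocks.push_back(blk);
  }
  return o;
}

// ---------- expression building ----------

static RF ast_eval(List ast, int nv) {
  std::string k = as<std::string>(ast["k"]);
  if (k == "n") return rf_const(nv, rat_from_str(as<std::string>(ast["v"])));
  if (k == "v") return rf_var(nv, as<int>(ast["i"]) - 1);
  if (k == "c") {
    std::string op = as<std::string>(ast["op"]);
    List args = ast["a"];
    if (op == "neg") return rf_neg(ast_eval(args[0], nv));
    if (op == "^") {
      RF b = ast_eval(args[0], nv);
      int e = as<int>(args[1]);
      bool inv = e < 0;
      if (inv) e = -e;
      RF r = rf_const(nv, Rat(1));
      for (int i = 0; i < e; ++i) r = rf_mul(r, b);
      if (inv) r = rf_div(rf_const(nv, Rat(1)), r);
      rf_trim(r);
      return r;
    }
    RF a = ast_eval(args[0], nv);
    RF b = ast_eval(args[1], nv);
    RF r;
    if (op == "+") r = rf_add(a, b);
    else if (op == "-") r = rf_sub(a, b);
    else if (op == "*") r = rf_mul(a, b);
    else if (op == "/") r = rf_div(a, b);
    else stop("unknown operator: " + op);
    rf_trim(r);
    return r;
  }
  stop("bad ast node");
}

// [[Rcpp::export]]
List eng_ast_to_rf(List ast, int nv) {
  RF r = ast_eval(ast, nv);
  rf_trim(r);
  return rf_to_r(r);
}

// [[Rcpp::export]]
List eng_rf_op(std::string op, List a, List b) {
  RF x = r_to_rf(a), y = r_to_rf(b), r;
  if (op == "+") r = rf_add(x, y);
  else if (op == "-") r = rf_sub(x, y);
  else if (op == "*") r = rf_mul(x, y);
  else if (op == "/") r = rf_div(x, y);
  else stop("unknown rf op");
  rf_trim(r);
  return rf_to_r(r);
}

// [[Rcpp::export]]
List eng_poly_op(std::string op, List a, List b) {
  PolyQ x = r_to_pq(a), y = r_to_pq(b);
  if (op == "+") return pq_to_r(pq_add(x, y));
  if (op == "-") return pq_to_r(pq_sub(x, y));
  if (op == "*") return pq_to_r(pq_mul(x, y));
  stop("unknown poly op");
}

// [[Rcpp::export]]
List eng_poly_scale(List a, std::string c) {
  return pq_to_r(pq_scale(r_to_pq(a), rat_from_str(c)));
}

// primitive integer form, positive leading coefficient (lex-leading term)
// [[Rcpp::export]]
List eng_poly_canon(List a) {
  PolyZ z = pq_to_pz(r_to_pq(a));
  Order lex;   // lex = singleton blocks over all vars
  for (int v = 0; v < z.nv; ++v) lex.blocks.push_back({v});
  pz_sort(z, lex);
  pz_normalize(z);
  return pq_to_r(pz_to_pq(z));
}

// [[Rcpp::export]]
List eng_poly_eval_partial(List a, IntegerVector vars, CharacterVector vals) {
  PolyQ q = r_to_pq(a);
  std::vector<int> vs;
  std::vector<Rat> xs;
  for (int i = 0; i < vars.size(); ++i) {
    vs.push_back(vars[i] - 1);
    xs.push_back(rat_from_str(as<std::string>(vals[i])));
  }
  return pq_to_r(pq_eval_partial(q, vs, xs));
}

// [[Rcpp::export]]
List eng_rf_eval(List f, CharacterVector vals) {
  RF r = r_to_rf(f);
  int nv = r.num.nv;
  std::vector<int> vs(nv);
  std::vector<Rat> xs(nv);
  for (int i = 0; i < nv; ++i) { vs[i] = i; xs[i] = rat_from_str(as<std::string>(vals[i])); }
  PolyQ n = pq_eval_partial(r.num, vs, xs);
  PolyQ d = pq_eval_partial(r.den, vs, xs);
  Rat nn = n.is0() ? Rat(0) : n.t.begin()->second;
  Rat dd = d.is0() ? Rat(0) : d.t.begin()->second;
  if (dd.is0()) return List::create(_["ok"] = false, _["value"] = "");
  return List::create(_["ok"] = true, _["value"] = rat_to_str(rdiv(nn, dd)));
}

// ---------- derivatives of outputs along the vector field ----------
// variable layout: x_1..x_n | u_{1,0..K} .. u_{r,0..K} | p_1..p_P

// [[Rcpp::export]]
List eng_total_derivs(List f, List g, int n, int r, int P, int maxord,
                      LogicalVector const_input) {
  int nv = n + r * (maxord + 1) + P;
  std::vector<RF> fr(n);
  for (int i = 0; i < n; ++i) fr[i] = r_to_rf(f[i]);
  List out(g.size());
  for (int j = 0; j < g.size(); ++j) {
    RF cur = r_to_rf(g[j]);
    List row(maxord + 1);
    row[0] = rf_to_r(cur);
    for (int k = 1; k <= maxord; ++k) {
      RF acc = rf_const(nv, Rat(0));
      // d/dv as rational function, times dv/dt
      auto add_part = [&](int v, const RF& vdot) {
        PolyQ dn = pq_deriv(cur.num, v), dd = pq_deriv(cur.den, v);
        if (dn.is0() && dd.is0()) return;
        RF dv;
        dv.num = pq_sub(pq_mul(dn, cur.den), pq_mul(cur.num, dd));
        dv.den = pq_mul(cur.den, cur.den);
        rf_trim(dv);
        acc = rf_add(acc, rf_mul(dv, vdot));
        rf_trim(acc);
      };
      for (int i = 0; i < n; ++i) add_part(i, fr[i]);
      for (int ui = 0; ui < r; ++ui) {
        if (const_input[ui]) continue;
        for (int l = 0; l < maxord; ++l) {
          int v = n + ui * (maxord + 1) + l;
          add_part(v, rf_var(nv, n + ui * (maxord + 1) + l + 1));
        }
      }
      cur = acc;
      row[k] = rf_to_r(cur);
      Rcpp::checkUserInterrupt();
    }
    out[j] = row;
  }
  return out;
}

// ---------- Groebner bases ----------

// [[Rcpp::export]]
List eng_groebner_z(List polys, List blocks, double max_steps, double max_seconds) {
  Order ord = r_to_order(blocks);
  GBLimit lim;
  lim.max_steps = (long)max_steps;
  lim.max_seconds = max_seconds;
  lim.start = std::chrono::steady_clock::now();
  std::vector<PolyZ> gens;
  for (int i = 0; i < polys.size(); ++i) gens.push_back(pq_to_pz(r_to_pq(polys[i])));
  std::vector<PolyZ> gb = buchberger_z(gens, ord, lim);
  List out(gb.size());
  for (size_t i = 0; i < gb.size(); ++i) out[i] = pq_to_r(pz_to_pq(gb[i]));
  return out;
}

// [[Rcpp::export]]
List eng_groebner_p(List polys, List blocks, double prime, double max_steps,
                    double max_seconds) {
  long long P = (long long)prime;
  Order ord = r_to_order(blocks);
  GBLimit lim;
  lim.max_steps = (long)max_steps;
  lim.max_seconds = max_seconds;
  lim.start = std::chrono::steady_clock::now();
  std::vector<PolyP> gens;
  for (int i = 0; i < polys.size(); ++i) {
    PolyP g = pz_to_pp(pq_to_pz(r_to_pq(polys[i])), P);
    if (!g.is0()) gens.push_back(g);
  }
  std::vector<PolyP> gb = buchberger_p(gens, ord, P, lim);
  List out(gb.size());
  for (size_t i = 0; i < gb.size(); ++i) {
    const PolyP& g = gb[i];
    int nt = (int)g.e.size();
    IntegerMatrix exp(nt, g.nv);
    NumericVector res(nt), rnum(nt), rden(nt);
    LogicalVector ok(nt);
    bool wide = P > 2147483647LL;
    for (int t = 0; t < nt; ++t) {
      for (int j = 0; j < g.nv; ++j) exp(t, j) = g.e[t][j];
      res[t] = (double)g.c[t];
      long long nn, dd;
      bool o = false;
      if (wide) {
        // wide prime: residues near 0 (mod P) are read as plain integers
        long long v = g.c[t] > P / 2 ? g.c[t] - P : g.c[t];
        if (std::llabs(v) <= 1000000000000LL) { nn = v; dd = 1; o = true; }
      }
      if (!o) o = rat_recon(g.c[t], P, nn, dd);
      ok[t] = o;
      rnum[t] = o ? (double)nn : NA_REAL;
      rden[t] = o ? (double)dd : NA_REAL;
    }
    out[i] = List::create(_["exp"] = exp, _["res"] = res, _["rnum"] = rnum,
                          _["rden"] = rden, _["ok"] = ok);
  }
  return out;
}

// ---------- univariate helpers mod p ----------

static std::vector<long long> upoly_trim(std::vector<long long> a) {
  while (!a.empty() && a.back() == 0) a.pop_back();
  return a;
}
static std::vector<long long> upoly_mod(std::vector<long long> a,
                                        const std::vector<long long>& b, long long P) {
  while (a.size() >= b.size() && !a.empty()) {
    long long c = p_mul(a.back(), p_inv(b.back(), P), P);
    size_t off = a.size() - b.size();
    for (size_t i = 0; i < b.size(); ++i)
      a[off + i] = ((a[off + i] - p_mul(c, b[i], P)) % P + P) % P;
    a = upoly_trim(a);
  }
  return a;
}
static std::vector<long long> upoly_gcd(std::vector<long long> a,
                                        std::vector<long long> b, long long P) {
  a = upoly_trim(a); b = upoly_trim(b);
  while (!b.empty()) {
    auto r = upoly_mod(a, b, P);
    a = b; b = r;
  }
  return a;
}

// number of distinct roots (over an algebraic closure) = degree of the
// squarefree part: deg f - deg gcd(f, f')
// [[Rcpp::export]]
int eng_sqfree_deg_p(NumericVector coefs, double prime) {
  long long P = (long long)prime;
  std::vector<long long> f;
  for (int i = 0; i < coefs.size(); ++i) f.push_back((((long long)coefs[i]) % P + P) % P);
  f = upoly_trim(f);
  if (f.size() <= 1) return 0;
  std::vector<long long> df;
  for (size_t i = 1; i < f.size(); ++i) df.push_back(p_mul(f[i], (long long)(i % P), P));
  df = upoly_trim(df);
  auto g = upoly_gcd(f, df, P);
  return (int)(f.size() - 1 - (g.empty() ? 0 : g.size() - 1));
}

// ---------- numeric linear algebra mod p ----------

// [[Rcpp::export]]
NumericMatrix eng_jacobian_p(List rfs, NumericVector point, double prime) {
  long long P = (long long)prime;
  int K = rfs.size();
  int nv = point.size();
  std::vector<Rat> xs(nv);
  std::vector<int> vs(nv);
  for (int i = 0; i < nv; ++i) { vs[i] = i; xs[i] = Rat((long long)point[i]); }
  NumericMatrix J(K, nv);
  for (int k = 0; k < K; ++k) {
    RF f = r_to_rf(rfs[k]);
    PolyQ dval = pq_eval_partial(f.den, vs, xs);
    Rat den = dval.is0() ? Rat(0) : dval.t.begin()->second;
    long long denm = den.is0() ? 0 : p_mul(mod_small(den.n, P), p_inv(mod_small(den.d, P), P), P);
    if (denm == 0) stop("denominator vanishes at evaluation point");
    PolyQ nval = pq_eval_partial(f.num, vs, xs);
    Rat num = nval.is0() ? Rat(0) : nval.t.begin()->second;
    long long numm = num.is0() ? 0 : p_mul(mod_small(num.n, P), p_inv(mod_small(num.d, P), P), P);
    for (int j = 0; j < nv; ++j) {
      PolyQ dn = pq_deriv(f.num, j), dd = pq_deriv(f.den, j);
      auto ev = [&](const PolyQ& q) -> long long {
        PolyQ v = pq_eval_partial(q, vs, xs);
        if (v.is0()) return 0;
        Rat c = v.t.begin()->second;
        return p_mul(mod_small(c.n, P), p_inv(mod_small(c.d, P), P), P);
      };
      long long dnm = ev(dn), ddm = ev(dd);
      // (dn*den - num*dd)/den^2
      long long t = ((dnm * denm - p_mul(numm, ddm, P)) % P + P) % P;
      J(k, j) = (double)p_mul(t, p_inv(p_mul(denm, denm, P), P), P);
    }
  }
  return J;
}

// [[Rcpp::export]]
int eng_rank_p(NumericMatrix m, double prime) {
  long long P = (long long)prime;
  int nr = m.nrow(), nc = m.ncol();
  std::vector<std::vector<long long>> a(nr, std::vector<long long>(nc));
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) a[i][j] = (((long long)m(i, j)) % P + P) % P;
  int rank = 0;
  for (int col = 0; col < nc && rank < nr; ++col) {
    int piv = -1;
    for (int i = rank; i < nr; ++i) if (a[i][col] != 0) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(a[piv], a[rank]);
    long long inv = p_inv(a[rank][col], P);
    for (int j = col; j < nc; ++j) a[rank][j] = p_mul(a[rank][j], inv, P);
    for (int i = 0; i < nr; ++i) {
      if (i == rank || a[i][col] == 0) continue;
      long long c = a[i][col];
      for (int j = col; j < nc; ++j)
        a[i][j] = ((a[i][j] - p_mul(c, a[rank][j], P)) % P + P) % P;
    }
    ++rank;
  }
  return rank;
}

// ---------- solve-and-substitute pre-elimination ----------
// States that occur linearly with a state-free coefficient are solved from
// one relation and pseudo-substituted into all others (multiplying by the
// appropriate power of the pivot coefficient, which the saturation step
// later constrains nonzero). For compartmental and most rational
// systems-biology models this removes every state without a Groebner basis;
// anything left over goes to Buchberger.

static int pq_maxdeg_var(const PolyQ& p, int v) {
  int d = 0;
  for (auto& kv : p.t) d = std::max(d, (int)kv.first[v]);
  return d;
}
static bool pq_has_state(const PolyQ& p, int nstates, int except = -1) {
  for (auto& kv : p.t)
    for (int i = 0; i < nstates; ++i)
      if (i != except && kv.first[i] > 0) return true;
  return false;
}
// split by power of variable v: out[k] = coefficient of v^k (v removed)
static std::vector<PolyQ> pq_split_var(const PolyQ& p, int v, int d) {
  std::vector<PolyQ> out(d + 1);
  for (auto& q : out) q.nv = p.nv;
  for (auto& kv : p.t) {
    Expo e = kv.first;
    int k = e[v];
    e[v] = 0;
    out[k].add_term(e, kv.second);
  }
  return out;
}
static PolyQ pq_strip(const PolyQ& p) {   // integer-primitive rational cleanup
  return pz_to_pq(pq_to_pz(p));
}

// exact multivariate division under the canonical lex order; ok=false if the
// remainder is nonzero
static PolyQ pq_exact_div(const PolyQ& f, const PolyQ& g, bool& ok) {
  PolyQ q; q.nv = f.nv;
  PolyQ h = f;
  const Expo& lg = g.t.begin()->first;
  const Rat& cg = g.t.begin()->second;
  while (!h.is0()) {
    const Expo& lh = h.t.begin()->first;
    if (!expo_divides(lg, lh)) { ok = false; return q; }
    Expo m = expo_sub(lh, lg);
    Rat c = rdiv(h.t.begin()->second, cg);
    q.add_term(m, c);
    // h -= c * x^m * g
    for (auto& kv : g.t) h.add_term(expo_add(kv.first, m), rneg(rmul(c, kv.second)));
  }
  ok = true;
  return q;
}

// divide out every pivot factor that divides exactly, repeatedly
static PolyQ pq_remove_factors(PolyQ f, const std::vector<PolyQ>& pivots) {
  bool any = true;
  while (any && !f.is0()) {
    any = false;
    for (const auto& piv : pivots) {
      if (piv.t.size() < 2 && expo_is1(piv.t.begin()->first)) continue;
      bool ok = false;
      PolyQ q = pq_exact_div(f, piv, ok);
      if (ok && !q.is0()) { f = q; any = true; }
    }
  }
  return f;
}

// [[Rcpp::export]]
List eng_presolve(List polys, int nstates, double max_steps) {
  std::vector<PolyQ> rels;
  for (int i = 0; i < polys.size(); ++i) {
    PolyQ q = pq_strip(r_to_pq(polys[i]));
    if (!q.is0()) rels.push_back(q);
  }
  int nv = rels.empty() ? 0 : rels[0].nv;
  std::vector<PolyQ> solves(nstates);
  std::vector<PolyQ> pivots;
  std::vector<bool> solved(nstates, false);
  long steps = 0;
  while (true) {
    // pick the smallest relation linear in an unsolved state with a
    // state-free linear coefficient
    int best_r = -1, best_s = -1;
    size_t best_sz = 0;
    for (size_t r = 0; r < rels.size(); ++r) {
      for (int s = 0; s < nstates; ++s) {
        if (solved[s]) continue;
        if (pq_maxdeg_var(rels[r], s) != 1) continue;
        auto parts = pq_split_var(rels[r], s, 1);
        if (pq_has_state(parts[1], nstates)) continue;
        if (best_r < 0 || rels[r].t.size() < best_sz) {
          best_r = (int)r; best_s = s; best_sz = rels[r].t.size();
        }
      }
    }
    if (best_r < 0) break;
    PolyQ pivot = rels[best_r];
    rels.erase(rels.begin() + best_r);
    auto parts = pq_split_var(pivot, best_s, 1);
    PolyQ A = parts[1], negB = pq_neg(parts[0]);
    auto substitute = [&](PolyQ& Q) {
      int d = pq_maxdeg_var(Q, best_s);
      if (d == 0) return;
      auto qk = pq_split_var(Q, best_s, d);
      // powers of A and -B
      std::vector<PolyQ> Ap(d + 1), Bp(d + 1);
      Ap[0] = pq_const(nv, Rat(1)); Bp[0] = pq_const(nv, Rat(1));
      for (int k = 1; k <= d; ++k) { Ap[k] = pq_mul(Ap[k - 1], A); Bp[k] = pq_mul(Bp[k - 1], negB); }
      PolyQ acc; acc.nv = nv;
      for (int k = 0; k <= d; ++k)
        acc = pq_add(acc, pq_mul(qk[k], pq_mul(Bp[k], Ap[d - k])));
      Q = pq_strip(acc);
      steps += (long)Q.t.size();
      if (max_steps > 0 && steps > (long)max_steps)
        stop("pre-elimination exceeded step budget");
      Rcpp::checkUserInterrupt();
    };
    for (auto& Q : rels) substitute(Q);
    for (int s = 0; s < nstates; ++s)
      if (solved[s]) substitute(solves[s]);
    solves[best_s] = pivot;
    solved[best_s] = true;
    if (!A.is0() && !(A.t.size() == 1 && expo_is1(A.t.begin()->first)))
      pivots.push_back(pq_strip(A));
  }
  List freeL, restL, solvesL(nstates);
  for (auto& Q : rels) {
    if (Q.is0()) continue;
    if (pq_has_state(Q, nstates)) restL.push_back(pq_to_r(pq_strip(Q)));
    else freeL.push_back(pq_to_r(pq_strip(pq_remove_factors(Q, pivots))));
  }
  for (int s = 0; s < nstates; ++s) {
    if (solved[s]) solvesL[s] = pq_to_r(pq_strip(pq_remove_factors(solves[s], pivots)));
    else solvesL[s] = R_NilValue;
  }
  return List::create(_["free"] = freeL, _["rest"] = restL, _["solves"] = solvesL);
}
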