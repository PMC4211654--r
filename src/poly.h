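// Multivariate polynomials: exact rational coefficients (PolyQ) for
// expression work, integer coefficients (PolyZ) for fraction-free Groebner
// computations over Q, and machine residues (PolyP) for computations mod a
// word-size prime. Monomial orders are block orders (graded reverse
// lexicographic inside each block); singleton blocks give plain lex.
#pragma once
#include "bigint.h"
#include <map>
#include <functional>

namespace icb {

typedef std::vector<uint16_t> Expo;

inline Expo expo_add(const Expo& a, const Expo& b) {
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = (uint16_t)(a[i] + b[i]);
  return r;
}
inline bool expo_divides(const Expo& a, const Expo& b) {   // a | b
  for (size_t i = 0; i < a.size(); ++i) if (a[i] > b[i]) return false;
  return true;
}
inline Expo expo_sub(const Expo& a, const Expo& b) {       // a - b (assumes b|a)
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = (uint16_t)(a[i] - b[i]);
  return r;
}
inline Expo expo_lcm(const Expo& a, const Expo& b) {
  Expo r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = std::max(a[i], b[i]);
  return r;
}
inline bool expo_is1(const Expo& a) {
  for (auto v : a) if (v) return false;
  return true;
}
inline bool expo_coprime(const Expo& a, const Expo& b) {
  for (size_t i = 0; i < a.size(); ++i) if (a[i] && b[i]) return false;
  return true;
}
inline int expo_totdeg(const Expo& a) { int t = 0; for (auto v : a) t += v; return t; }

struct Order {
  std::vector<std::vector<int>> blocks;  // 0-based variable indices
  // 1 if a > b, -1 if a < b, 0 equal (restricted to block vars; exps outside
  // every block are ignored -- callers must cover all vars)
  int cmp(const Expo& a, const Expo& b) const {
    for (const auto& blk : blocks) {
      int da = 0, db = 0;
      for (int v : blk) { da += a[v]; db += b[v]; }
      if (da != db) return da > db ? 1 : -1;
      // grevlex tie-break: last variable of the block where exponents
      // differ; the one with the SMALLER exponent there is larger
      for (size_t i = blk.size(); i-- > 0;) {
        int v = blk[i];
        if (a[v] != b[v]) return a[v] < b[v] ? 1 : -1;
      }
    }
    return 0;
  }
};

// ------------------------------------------------------------------
// PolyQ: map-based, canonical (descending lex on exponent vectors)
struct LexGt {
  bool operator()(const Expo& a, const Expo& b) const { return a > b; }
};
struct PolyQ {
  int nv = 0;
  std::map<Expo, Rat, LexGt> t;
  void add_term(const Expo& e, const Rat& c) {
    if (c.is0()) return;
    auto it = t.find(e);
    if (it == t.end()) t.emplace(e, c);
    else {
      it->second = radd(it->second, c);
      if (it->second.is0()) t.erase(it);
    }
  }
  bool is0() const { return t.empty(); }
};

inline PolyQ pq_const(int nv, const Rat& c) {
  PolyQ p; p.nv = nv;
  p.add_term(Expo(nv, 0), c);
  return p;
}
inline PolyQ pq_var(int nv, int i) {
  PolyQ p; p.nv = nv;
  Expo e(nv, 0); e[i] = 1;
  p.add_term(e, Rat(1));
  return p;
}
inline PolyQ pq_add(const PolyQ& a, const PolyQ& b) {
  PolyQ r = a;
  for (auto& kv : b.t) r.add_term(kv.first, kv.second);
  return r;
}
inline PolyQ pq_neg(const PolyQ& a) {
  PolyQ r = a;
  for (auto& kv : r.t) kv.second = rneg(kv.second);
  return r;
}
inline PolyQ pq_sub(const PolyQ& a, const PolyQ& b) { return pq_add(a, pq_neg(b)); }
inline PolyQ pq_mul(const PolyQ& a, const PolyQ& b) {
  PolyQ r; r.nv = a.nv;
  for (auto& ka : a.t)
    for (auto& kb : b.t)
      r.add_term(expo_add(ka.first, kb.first), rmul(ka.second, kb.second));
  return r;
}
inline PolyQ pq_scale(const PolyQ& a, const Rat& c) {
  PolyQ r; r.nv = a.nv;
  if (c.is0()) return r;
  for (auto& kv : a.t) r.t.emplace(kv.first, rmul(kv.second, c));
  return r;
}
inline PolyQ pq_pow(const PolyQ& a, int k) {
  PolyQ r = pq_const(a.nv, Rat(1));
  for (int i = 0; i < k; ++i) r = pq_mul(r, a);
  return r;
}
inline PolyQ pq_deriv(const PolyQ& a, int var) {
  PolyQ r; r.nv = a.nv;
  for (auto& kv : a.t) {
    if (kv.first[var] == 0) continue;
    Expo e = kv.first;
    int k = e[var]; e[var]--;
    r.add_term(e, rmul(kv.second, Rat(k)));
  }
  return r;
}
// substitute values (rationals) for a subset of variables, keep others
inline PolyQ pq_eval_partial(const PolyQ& a, const std::vector<int>& vars,
                             const std::vector<Rat>& vals) {
  std::vector<int> which(a.nv, -1);
  for (size_t i = 0; i < vars.size(); ++i) which[vars[i]] = (int)i;
  PolyQ r; r.nv = a.nv;
  for (auto& kv : a.t) {
    Rat c = kv.second;
    Expo e = kv.first;
    for (int v = 0; v < a.nv; ++v) {
      if (which[v] >= 0 && e[v] > 0) {
        for (int k = 0; k < e[v]; ++k) c = rmul(c, vals[which[v]]);
        e[v] = 0;
      }
    }
    r.add_term(e, c);
  }
  return r;
}

// rational function as num/den pair
struct RF { PolyQ num, den; };
inline RF rf_const(int nv, const Rat& c) { return {pq_const(nv, c), pq_const(nv, Rat(1))}; }
inline RF rf_var(int nv, int i) { return {pq_var(nv, i), pq_const(nv, Rat(1))}; }
inline RF rf_add(const RF& a, const RF& b) {
  return {pq_add(pq_mul(a.num, b.den), pq_mul(b.num, a.den)), pq_mul(a.den, b.den)};
}
inline RF rf_sub(const RF& a, const RF& b) {
  return {pq_sub(pq_mul(a.num, b.den), pq_mul(b.num, a.den)), pq_mul(a.den, b.den)};
}
inline RF rf_mul(const RF& a, const RF& b) { return {pq_mul(a.num, b.num), pq_mul(a.den, b.den)}; }
inline RF rf_div(const RF& a, const RF& b) {
  if (b.num.is0()) throw std::runtime_error("division by zero expression");
  return {pq_mul(a.num, b.den), pq_mul(a.den, b.num)};
}
inline RF rf_neg(const RF& a) { return {pq_neg(a.num), a.den}; }

// crude size control: divide out shared monomial content and shared rational factor
inline void rf_trim(RF& a) {
  if (a.num.is0()) { a.den = pq_const(a.den.nv, Rat(1)); return; }
  int nv = a.num.nv;
  Expo g(nv, (uint16_t)0xffff);
  auto upd = [&](const PolyQ& p) {
    for (auto& kv : p.t)
      for (int v = 0; v < nv; ++v) g[v] = std::min(g[v], kv.first[v]);
  };
  upd(a.num); upd(a.den);
  bool nz = false; for (auto v : g) if (v) { nz = true; break; }
  if (nz) {
    PolyQ n2; n2.nv = nv; PolyQ d2; d2.nv = nv;
    for (auto& kv : a.num.t) n2.t.emplace(expo_sub(kv.first, g), kv.second);
    for (auto& kv : a.den.t) d2.t.emplace(expo_sub(kv.first, g), kv.second);
    a.num = n2; a.den = d2;
  }
  const Rat& lc = a.den.t.begin()->second;
  if (!(is1(lc.n) && is1(lc.d))) {
    Rat inv = rdiv(Rat(1), lc);
    a.num = pq_scale(a.num, inv);
    a.den = pq_scale(a.den, inv);
  }
}

// ------------------------------------------------------------------
// PolyZ: vector-based, sorted descending under an Order; integer coeffs
struct PolyZ {
  int nv = 0;
  std::vector<Expo> e;
  std::vector<BI> c;
  bool is0() const { return e.empty(); }
};

inline void pz_sort(PolyZ& p, const Order& ord) {
  std::vector<size_t> idx(p.e.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    int c2 = ord.cmp(p.e[a], p.e[b]);
    if (c2 != 0) return c2 > 0;
    return p.e[a] > p.e[b];
  });
  std::vector<Expo> e2(idx.size());
  std::vector<BI> c2(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) { e2[i] = p.e[idx[i]]; c2[i] = p.c[idx[i]]; }
  p.e = e2; p.c = c2;
}

// clear denominators, remove integer content, make leading coeff positive
inline PolyZ pq_to_pz(const PolyQ& q) {
  PolyZ r; r.nv = q.nv;
  if (q.is0()) return r;
  BI den(1);
  for (auto& kv : q.t) {
    BI g = gcd(den, kv.second.d);
    BI qq, rr;
    divmod(kv.second.d, g, qq, rr);
    den = mul(den, qq);
  }
  for (auto& kv : q.t) {
    BI qq, rr;
    divmod(den, kv.second.d, qq, rr);
    r.e.push_back(kv.first);
    r.c.push_back(mul(kv.second.n, qq));
  }
  return r;
}

inline void pz_normalize(PolyZ& p) {   // primitive part, positive lead (index 0)
  if (p.is0()) return;
  BI g(0);
  for (auto& c : p.c) { g = gcd(g, c); if (is1(g)) break; }
  bool flip = p.c[0].s < 0;
  if (!is1(g) || flip) {
    for (auto& c : p.c) {
      if (!is1(g)) { BI q, r; divmod(c, g, q, r); c = q; }
      if (flip) c.s = -c.s;
    }
  }
}

inline PolyQ pz_to_pq(const PolyZ& p) {
  PolyQ r; r.nv = p.nv;
  for (size_t i = 0; i < p.e.size(); ++i) r.t.emplace(p.e[i], Rat(p.c[i], BI(1)));
  return r;
}

// a*f - b*(x^m * g), result sorted under ord (f, g sorted under ord)
inline PolyZ pz_axpy(const PolyZ& f, const BI& a, const BI& b, const Expo& m,
                     const PolyZ& g, const Order& ord) {
  PolyZ r; r.nv = f.nv;
  size_t i = 0, j = 0;
  r.e.reserve(f.e.size() + g.e.size());
  while (i < f.e.size() || j < g.e.size()) {
    int cmp;
    Expo ge;
    if (j < g.e.size()) ge = expo_add(g.e[j], m);
    if (i >= f.e.size()) cmp = -1;
    else if (j >= g.e.size()) cmp = 1;
    else {
      cmp = ord.cmp(f.e[i], ge);
      if (cmp == 0) cmp = f.e[i] > ge ? 1 : (f.e[i] < ge ? -1 : 0);
    }
    if (cmp > 0) { r.e.push_back(f.e[i]); r.c.push_back(mul(a, f.c[i])); ++i; }
    else if (cmp < 0) { r.e.push_back(ge); r.c.push_back(neg(mul(b, g.c[j]))); ++j; }
    else {
      BI v = sub(mul(a, f.c[i]), mul(b, g.c[j]));
      if (!v.is0()) { r.e.push_back(f.e[i]); r.c.push_back(v); }
      ++i; ++j;
    }
  }
  return r;
}

// ------------------------------------------------------------------
// PolyP: residues mod word prime
struct PolyP {
  int nv = 0;
  std::vector<Expo> e;
  std::vector<long long> c;
  bool is0() const { return e.empty(); }
};

inline long long p_mul(long long a, long long b, long long P) {
  if (P > 2147483647LL) return (long long)((__int128)a * b % P);
  return (a * b) % P;
}
inline long long p_pow(long long a, long long k, long long P) {
  long long r = 1; a %= P;
  while (k) { if (k & 1) r = p_mul(r, a, P); a = p_mul(a, a, P); k >>= 1; }
  return r;
}
inline long long p_inv(long long a, long long P) { return p_pow(((a % P) + P) % P, P - 2, P); }

inline PolyP pz_to_pp(const PolyZ& p, long long P) {
  PolyP r; r.nv = p.nv;
  for (size_t i = 0; i < p.e.size(); ++i) {
    long long v = mod_small(p.c[i], P);
    if (v != 0) { r.e.push_back(p.e[i]); r.c.push_back(v); }
  }
  return r;
}

inline void pp_sort(PolyP& p, const Order& ord) {
  std::vector<size_t> idx(p.e.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    int c2 = ord.cmp(p.e[a], p.e[b]);
    if (c2 != 0) return c2 > 0;
    return p.e[a] > p.e[b];
  });
  std::vector<Expo> e2(idx.size());
  std::vector<long long> c2(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) { e2[i] = p.e[idx[i]]; c2[i] = p.c[idx[i]]; }
  p.e = e2; p.c = c2;
}

inline void pp_monic(PolyP& p, long long P) {
  if (p.is0()) return;
  long long inv = p_inv(p.c[0], P);
  for (auto& c : p.c) c = p_mul(c, inv, P);
}

inline PolyP pp_axpy(const PolyP& f, long long b, const Expo& m, const PolyP& g,
                     const Order& ord, long long P) {
  // f - b * x^m * g  (g monic leading handled by caller's b)
  PolyP r; r.nv = f.nv;
  size_t i = 0, j = 0;
  r.e.reserve(f.e.size() + g.e.size());
  while (i < f.e.size() || j < g.e.size()) {
    int cmp;
    Expo ge;
    if (j < g.e.size()) ge = expo_add(g.e[j], m);
    if (i >= f.e.size()) cmp = -1;
    else if (j >= g.e.size()) cmp = 1;
    else {
      cmp = ord.cmp(f.e[i], ge);
      if (cmp == 0) cmp = f.e[i] > ge ? 1 : (f.e[i] < ge ? -1 : 0);
    }
    if (cmp > 0) { r.e.push_back(f.e[i]); r.c.push_back(f.c[i]); ++i; }
    else if (cmp < 0) { r.e.push_back(ge); r.c.push_back((P - p_mul(b, g.c[j], P)) % P); ++j; }
    else {
      long long v = (f.c[i] - p_mul(b, g.c[j], P) % P + P) % P;
      if (v != 0) { r.e.push_back(f.e[i]); r.c.push_back(v); }
      ++i; ++j;
    }
  }
  return r;
}

} // namespace icb
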