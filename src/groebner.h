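// Buchberger's algorithm: fraction-free over the integers (primitive-part
// normalization) and monic over GF(p). Normal pair-selection strategy with
// the coprimality and chain criteria; a step guard bounds runaway bases.
#pragma once
#include "poly.h"
#include <set>
#include <chrono>

namespace icb {

struct GBLimit {
  long max_steps = 2000000;     // reduction steps across the whole run
  double max_seconds = 0;       // 0 = unlimited
  std::chrono::steady_clock::time_point start;
  long steps = 0;
  void tick(long k = 1) {
    steps += k;
    if (max_steps > 0 && steps > max_steps)
      throw std::runtime_error("groebner basis computation exceeded step budget");
    if (max_seconds > 0 && (steps & 1023) == 0) {
      double el = std::chrono::duration<double>(std::chrono::steady_clock::now() - start).count();
      if (el > max_seconds)
        throw std::runtime_error("groebner basis computation exceeded time budget");
    }
  }
};

// ---------------- integer (fraction-free) version ----------------

inline PolyZ nf_z(PolyZ f, const std::vector<PolyZ>& basis, const Order& ord,
                  GBLimit& lim, bool full = true) {
  size_t scan = 0;    // index of highest unreduced term of f
  while (!f.is0() && scan < f.e.size()) {
    bool reduced = false;
    for (const auto& g : basis) {
      if (g.is0()) continue;
      if (expo_divides(g.e[0], f.e[scan])) {
        Expo m = expo_sub(f.e[scan], g.e[0]);
        BI a = g.c[0]; BI b = f.c[scan];
        if (a.s < 0) { a.s = -a.s; b.s = -b.s; }
        PolyZ head; head.nv = f.nv;   // keep already-fully-reduced prefix intact
        for (size_t i = 0; i < scan; ++i) { head.e.push_back(f.e[i]); head.c.push_back(mul(a, f.c[i])); }
        PolyZ tail; tail.nv = f.nv;
        for (size_t i = scan; i < f.e.size(); ++i) { tail.e.push_back(f.e[i]); tail.c.push_back(f.c[i]); }
        PolyZ nt = pz_axpy(tail, a, b, m, g, ord);
        head.e.insert(head.e.end(), nt.e.begin(), nt.e.end());
        head.c.insert(head.c.end(), nt.c.begin(), nt.c.end());
        f = head;
        pz_normalize(f);
        lim.tick();
        reduced = true;
        break;
      }
    }
    if (!reduced) {
      if (!full) break;
      ++scan;
    }
  }
  pz_normalize(f);
  return f;
}

inline PolyZ spoly_z(const PolyZ& f, const PolyZ& g, const Order& ord) {
  Expo l = expo_lcm(f.e[0], g.e[0]);
  Expo mf = expo_sub(l, f.e[0]), mg = expo_sub(l, g.e[0]);
  // g.c[0]*x^mf*f - f.c[0]*x^mg*g
  PolyZ sf; sf.nv = f.nv;
  for (size_t i = 0; i < f.e.size(); ++i) { sf.e.push_back(expo_add(f.e[i], mf)); sf.c.push_back(f.c[i]); }
  PolyZ r = pz_axpy(sf, g.c[0], f.c[0], mg, g, ord);
  pz_normalize(r);
  return r;
}

inline std::vector<PolyZ> interreduce_z(std::vector<PolyZ> basis, const Order& ord, GBLimit& lim) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t i = 0; i < basis.size(); ++i) {
      if (basis[i].is0()) continue;
      std::vector<PolyZ> others;
      for (size_t j = 0; j < basis.size(); ++j)
        if (j != i && !basis[j].is0()) others.push_back(basis[j]);
      PolyZ r = nf_z(basis[i], others, ord, lim, true);
      if (r.e != basis[i].e || r.is0()) changed = true;
      basis[i] = r;
    }
  }
  std::vector<PolyZ> out;
  for (auto& b : basis) if (!b.is0()) out.push_back(b);
  std::sort(out.begin(), out.end(), [&](const PolyZ& a, const PolyZ& b) {
    int c = ord.cmp(a.e[0], b.e[0]);
    if (c != 0) return c < 0;
    return a.e.size() < b.e.size();
  });
  return out;
}

inline std::vector<PolyZ> buchberger_z(std::vector<PolyZ> gens, const Order& ord, GBLimit& lim) {
  std::vector<PolyZ> basis;
  for (auto& g : gens) {
    pz_sort(g, ord);
    pz_normalize(g);
    if (!g.is0()) basis.push_back(g);
  }
  typedef std::pair<size_t, size_t> Pair;
  auto lcm_deg = [&](const Pair& p) {
    return expo_totdeg(expo_lcm(basis[p.first].e[0], basis[p.second].e[0]));
  };
  std::vector<Pair> pairs;
  for (size_t i = 0; i < basis.size(); ++i)
    for (size_t j = i + 1; j < basis.size(); ++j) pairs.push_back({i, j});
  while (!pairs.empty()) {
    size_t best = 0;
    int bd = lcm_deg(pairs[0]);
    for (size_t k = 1; k < pairs.size(); ++k) {
      int d = lcm_deg(pairs[k]);
      if (d < bd) { bd = d; best = k; }
    }
    Pair pr = pairs[best];
    pairs.erase(pairs.begin() + best);
    const PolyZ& f = basis[pr.first];
    const PolyZ& g = basis[pr.second];
    if (expo_coprime(f.e[0], g.e[0])) continue;
    // chain criterion: some other basis element's lead divides the lcm and
    // both associated pairs are no longer pending
    Expo l = expo_lcm(f.e[0], g.e[0]);
    bool skip = false;
    for (size_t k = 0; k < basis.size(); ++k) {
      if (k == pr.first || k == pr.second || basis[k].is0()) continue;
      if (!expo_divides(basis[k].e[0], l)) continue;
      bool pend = false;
      for (auto& q : pairs) {
        if ((q.first == std::min(k, pr.first) && q.second == std::max(k, pr.first)) ||
            (q.first == std::min(k, pr.second) && q.second == std::max(k, pr.second))) { pend = true; break; }
      }
      if (!pend) { skip = true; break; }
    }
    if (skip) continue;
    PolyZ s = spoly_z(f, g, ord);
    PolyZ r = nf_z(s, basis, ord, lim, true);
    if (!r.is0()) {
      size_t newi = basis.size();
      basis.push_back(r);
      for (size_t i = 0; i < newi; ++i)
        if (!basis[i].is0()) pairs.push_back({i, newi});
    }
  }
  return interreduce_z(basis, ord, lim);
}

// ---------------- GF(p) version ----------------

inline PolyP nf_p(PolyP f, const std::vector<PolyP>& basis, const Order& ord,
                  long long P, GBLimit& lim, bool full = true) {
  size_t scan = 0;
  while (!f.is0() && scan < f.e.size()) {
    bool reduced = false;
    for (const auto& g : basis) {
      if (g.is0()) continue;
      if (expo_divides(g.e[0], f.e[scan])) {
        Expo m = expo_sub(f.e[scan], g.e[0]);
        long long b = p_mul(f.c[scan], p_inv(g.c[0], P), P);
        PolyP head; head.nv = f.nv;
        for (size_t i = 0; i < scan; ++i) { head.e.push_back(f.e[i]); head.c.push_back(f.c[i]); }
        PolyP tail; tail.nv = f.nv;
        for (size_t i = scan; i < f.e.size(); ++i) { tail.e.push_back(f.e[i]); tail.c.push_back(f.c[i]); }
        PolyP nt = pp_axpy(tail, b, m, g, ord, P);
        head.e.insert(head.e.end(), nt.e.begin(), nt.e.end());
        head.c.insert(head.c.end(), nt.c.begin(), nt.c.end());
        f = head;
        lim.tick();
        reduced = true;
        break;
      }
    }
    if (!reduced) {
      if (!full) break;
      ++scan;
    }
  }
  return f;
}

inline PolyP spoly_p(const PolyP& f, const PolyP& g, const Order& ord, long long P) {
  Expo l = expo_lcm(f.e[0], g.e[0]);
  Expo mf = expo_sub(l, f.e[0]), mg = expo_sub(l, g.e[0]);
  PolyP sf; sf.nv = f.nv;
  long long scale = p_inv(f.c[0], P);
  for (size_t i = 0; i < f.e.size(); ++i) { sf.e.push_back(expo_add(f.e[i], mf)); sf.c.push_back(p_mul(f.c[i], scale, P)); }
  long long b = p_inv(g.c[0], P);
  PolyP gg = g;
  for (auto& c : gg.c) c = p_mul(c, b, P);
  return pp_axpy(sf, 1, mg, gg, ord, P);
}

inline std::vector<PolyP> interreduce_p(std::vector<PolyP> basis, const Order& ord,
                                        long long P, GBLimit& lim) {
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t i = 0; i < basis.size(); ++i) {
      if (basis[i].is0()) continue;
      std::vector<PolyP> others;
      for (size_t j = 0; j < basis.size(); ++j)
        if (j != i && !basis[j].is0()) others.push_back(basis[j]);
      PolyP r = nf_p(basis[i], others, ord, P, lim, true);
      if (r.e != basis[i].e) changed = true;
      basis[i] = r;
    }
  }
  std::vector<PolyP> out;
  for (auto& b : basis) if (!b.is0()) { pp_monic(b, P); out.push_back(b); }
  std::sort(out.begin(), out.end(), [&](const PolyP& a, const PolyP& b) {
    int c = ord.cmp(a.e[0], b.e[0]);
    if (c != 0) return c < 0;
    return a.e.size() < b.e.size();
  });
  return out;
}

inline std::vector<PolyP> buchberger_p(std::vector<PolyP> gens, const Order& ord,
                                       long long P, GBLimit& lim) {
  std::vector<PolyP> basis;
  for (auto& g : gens) {
    pp_sort(g, ord);
    if (!g.is0()) { pp_monic(g, P); basis.push_back(g); }
  }
  typedef std::pair<size_t, size_t> Pair;
  std::vector<Pair> pairs;
  for (size_t i = 0; i < basis.size(); ++i)
    for (size_t j = i + 1; j < basis.size(); ++j) pairs.push_back({i, j});
  auto lcm_deg = [&](const Pair& p) {
    return expo_totdeg(expo_lcm(basis[p.first].e[0], basis[p.second].e[0]));
  };
  while (!pairs.empty()) {
    size_t best = 0;
    int bd = lcm_deg(pairs[0]);
    for (size_t k = 1; k < pairs.size(); ++k) {
      int d = lcm_deg(pairs[k]);
      if (d < bd) { bd = d; best = k; }
    }
    Pair pr = pairs[best];
    pairs.erase(pairs.begin() + best);
    const PolyP& f = basis[pr.first];
    const PolyP& g = basis[pr.second];
    if (expo_coprime(f.e[0], g.e[0])) continue;
    Expo l = expo_lcm(f.e[0], g.e[0]);
    bool skip = false;
    for (size_t k = 0; k < basis.size(); ++k) {
      if (k == pr.first || k == pr.second || basis[k].is0()) continue;
      if (!expo_divides(basis[k].e[0], l)) continue;
      bool pend = false;
      for (auto& q : pairs) {
        if ((q.first == std::min(k, pr.first) && q.second == std::max(k, pr.first)) ||
            (q.first == std::min(k, pr.second) && q.second == std::max(k, pr.second))) { pend = true; break; }
      }
      if (!pend) { skip = true; break; }
    }
    if (skip) continue;
    PolyP s = spoly_p(f, g, ord, P);
    PolyP r = nf_p(s, basis, ord, P, lim, true);
    if (!r.is0()) {
      pp_monic(r, P);
      size_t newi = basis.size();
      basis.push_back(r);
      for (size_t i = 0; i < newi; ++i)
        if (!basis[i].is0()) pairs.push_back({i, newi});
    }
  }
  return interreduce_p(basis, ord, P, lim);
}

// rational reconstruction of r mod P; bound ~ sqrt(P/2)
inline bool rat_recon(long long r, long long P, long long& num, long long& den) {
  long long B = (long long)std::max(1.0, std::floor(std::sqrt((double)P / 2.0)));
  long long a0 = P, a1 = ((r % P) + P) % P, t0 = 0, t1 = 1;
  while (a1 > B) {
    long long q = a0 / a1;
    long long a2 = a0 - q * a1; a0 = a1; a1 = a2;
    long long t2 = t0 - q * t1; t0 = t1; t1 = t2;
  }
  if (t1 == 0 || std::llabs(t1) > B) return false;
  num = a1; den = t1;
  if (den < 0) { den = -den; num = -num; }
  // num/den must actually reduce to r
  long long g = std::__gcd(std::llabs(num), den);
  if (g > 1) { num /= g; den /= g; }
  if (((__int128)den * r - num) % P != 0) return false;
  return true;
}

} // namespace icb
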