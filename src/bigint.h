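// Arbitrary-precision signed integers and rationals.
// Little-endian base 2^32 magnitude; division is Knuth algorithm D.
#pragma once
#include <vector>
#include <cstdint>
#include <string>
#include <stdexcept>
#include <algorithm>

namespace icb {

struct BI {
  int s = 0;                    // -1, 0, +1
  std::vector<uint32_t> d;      // magnitude, little-endian, no leading zeros

  BI() {}
  BI(long long v) {
    if (v == 0) { s = 0; return; }
    s = v > 0 ? 1 : -1;
    unsigned long long a = v > 0 ? (unsigned long long)v : (unsigned long long)(-(v + 1)) + 1ULL;
    while (a) { d.push_back((uint32_t)(a & 0xffffffffULL)); a >>= 32; }
  }
  bool is0() const { return s == 0; }
  void trim() {
    while (!d.empty() && d.back() == 0) d.pop_back();
    if (d.empty()) s = 0;
  }
};

inline int cmp_abs(const BI& a, const BI& b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;)
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  return 0;
}

inline BI add_abs(const BI& a, const BI& b) {
  BI r; r.s = 1;
  size_t n = std::max(a.d.size(), b.d.size());
  r.d.resize(n, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t t = carry;
    if (i < a.d.size()) t += a.d[i];
    if (i < b.d.size()) t += b.d[i];
    r.d[i] = (uint32_t)(t & 0xffffffffULL);
    carry = t >> 32;
  }
  if (carry) r.d.push_back((uint32_t)carry);
  return r;
}

// requires |a| >= |b|
inline BI sub_abs(const BI& a, const BI& b) {
  BI r; r.s = 1;
  r.d.resize(a.d.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.d.size(); ++i) {
    int64_t t = (int64_t)a.d[i] - borrow - (i < b.d.size() ? (int64_t)b.d[i] : 0);
    if (t < 0) { t += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r.d[i] = (uint32_t)t;
  }
  r.trim();
  return r;
}

inline BI neg(const BI& a) { BI r = a; r.s = -r.s; return r; }

inline BI add(const BI& a, const BI& b) {
  if (a.is0()) return b;
  if (b.is0()) return a;
  if (a.s == b.s) { BI r = add_abs(a, b); r.s = a.s; return r; }
  int c = cmp_abs(a, b);
  if (c == 0) return BI();
  BI r = c > 0 ? sub_abs(a, b) : sub_abs(b, a);
  r.s = c > 0 ? a.s : b.s;
  return r;
}

inline BI sub(const BI& a, const BI& b) { return add(a, neg(b)); }

inline BI mul(const BI& a, const BI& b) {
  if (a.is0() || b.is0()) return BI();
  BI r; r.s = a.s * b.s;
  r.d.assign(a.d.size() + b.d.size(), 0);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.d.size(); ++j) {
      uint64_t t = (uint64_t)a.d[i] * b.d[j] + r.d[i + j] + carry;
      r.d[i + j] = (uint32_t)(t & 0xffffffffULL);
      carry = t >> 32;
    }
    size_t k = i + b.d.size();
    while (carry) {
      uint64_t t = (uint64_t)r.d[k] + carry;
      r.d[k] = (uint32_t)(t & 0xffffffffULL);
      carry = t >> 32; ++k;
    }
  }
  r.trim();
  return r;
}

inline BI mul_small(const BI& a, uint32_t m) {
  if (a.is0() || m == 0) return BI();
  BI r; r.s = a.s;
  r.d.resize(a.d.size(), 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t t = (uint64_t)a.d[i] * m + carry;
    r.d[i] = (uint32_t)(t & 0xffffffffULL);
    carry = t >> 32;
  }
  if (carry) r.d.push_back((uint32_t)carry);
  return r;
}

// divide magnitude by small, return remainder
inline uint32_t divmod_small(const BI& a, uint32_t m, BI& q) {
  q.d.assign(a.d.size(), 0);
  q.s = a.s;
  uint64_t rem = 0;
  for (size_t i = a.d.size(); i-- > 0;) {
    uint64_t cur = (rem << 32) | a.d[i];
    q.d[i] = (uint32_t)(cur / m);
    rem = cur % m;
  }
  q.trim();
  return (uint32_t)rem;
}

// Knuth algorithm D on magnitudes: a = q*b + r, 0 <= r < |b|
inline void divmod_abs(const BI& a, const BI& b, BI& q, BI& r) {
  if (b.is0()) throw std::runtime_error("bigint division by zero");
  if (cmp_abs(a, b) < 0) { q = BI(); r = a; r.s = a.is0() ? 0 : 1; return; }
  if (b.d.size() == 1) {
    uint32_t rem = divmod_small(a, b.d[0], q);
    q.s = 1; q.trim();
    r = BI((long long)rem);
    return;
  }
  // normalize
  int shift = 0;
  uint32_t top = b.d.back();
  while (!(top & 0x80000000u)) { top <<= 1; ++shift; }
  auto shl = [&](const std::vector<uint32_t>& x) {
    std::vector<uint32_t> y(x.size() + 1, 0);
    for (size_t i = 0; i < x.size(); ++i) {
      y[i] |= (uint32_t)((uint64_t)x[i] << shift);
      y[i + 1] = shift ? (uint32_t)((uint64_t)x[i] >> (32 - shift)) : 0;
    }
    while (y.size() > 1 && y.back() == 0 && y.size() > x.size()) {
      if (y.back() == 0) y.pop_back(); else break;
    }
    return y;
  };
  std::vector<uint32_t> u = shl(a.d), v = shl(b.d);
  while (v.size() > 1 && v.back() == 0) v.pop_back();
  size_t n = v.size(), m = u.size() >= n ? u.size() - n : 0;
  if (u.size() < n + 1) u.resize(n + 1, 0);
  if (u.size() < m + n + 1) u.resize(m + n + 1, 0);
  q.d.assign(m + 1, 0);
  uint64_t vn1 = v[n - 1], vn2 = n >= 2 ? v[n - 2] : 0;
  for (size_t j = m + 1; j-- > 0;) {
    uint64_t num = ((uint64_t)u[j + n] << 32) | u[j + n - 1];
    uint64_t qhat = num / vn1, rhat = num % vn1;
    while (qhat >= (1ULL << 32) ||
           qhat * vn2 > ((rhat << 32) | (n >= 2 ? u[j + n - 2] : 0))) {
      --qhat; rhat += vn1;
      if (rhat >= (1ULL << 32)) break;
    }
    // multiply-subtract
    int64_t borrow = 0; uint64_t carry = 0;
    for (size_t i = 0; i < n; ++i) {
      uint64_t p = qhat * v[i] + carry;
      carry = p >> 32;
      int64_t t = (int64_t)u[i + j] - (int64_t)(p & 0xffffffffULL) - borrow;
      if (t < 0) { t += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
      u[i + j] = (uint32_t)t;
    }
    int64_t t = (int64_t)u[j + n] - (int64_t)carry - borrow;
    if (t < 0) {
      // add back
      t += ((int64_t)1 << 32);
      u[j + n] = (uint32_t)t;
      --qhat;
      uint64_t c2 = 0;
      for (size_t i = 0; i < n; ++i) {
        uint64_t s2 = (uint64_t)u[i + j] + v[i] + c2;
        u[i + j] = (uint32_t)(s2 & 0xffffffffULL);
        c2 = s2 >> 32;
      }
      u[j + n] = (uint32_t)(u[j + n] + c2);
    } else u[j + n] = (uint32_t)t;
    q.d[j] = (uint32_t)qhat;
  }
  q.s = 1; q.trim();
  // denormalize remainder
  r.d.assign(n, 0);
  for (size_t i = 0; i < n; ++i) {
    uint64_t lo = (uint64_t)u[i] >> shift;
    uint64_t hi = (shift && i + 1 < u.size()) ? ((uint64_t)u[i + 1] << (32 - shift)) : 0;
    r.d[i] = (uint32_t)((lo | hi) & 0xffffffffULL);
  }
  r.s = 1; r.trim();
}

// truncated division with signs: a = q*b + r, sign(r) = sign(a)
inline void divmod(const BI& a, const BI& b, BI& q, BI& r) {
  BI qa, ra;
  BI aa = a; aa.s = aa.is0() ? 0 : 1;
  BI bb = b; bb.s = bb.is0() ? 0 : 1;
  divmod_abs(aa, bb, qa, ra);
  q = qa; if (!q.is0()) q.s = a.s * b.s;
  r = ra; if (!r.is0()) r.s = a.s;
}

inline BI gcd(BI a, BI b) {
  a.s = a.is0() ? 0 : 1;
  b.s = b.is0() ? 0 : 1;
  while (!b.is0()) {
    BI q, r;
    divmod_abs(a, b, q, r);
    a = b; b = r;
  }
  if (a.is0()) return BI(0);
  a.s = 1;
  return a;
}

inline bool is1(const BI& a) { return a.s == 1 && a.d.size() == 1 && a.d[0] == 1; }

inline BI from_dec(const std::string& str) {
  BI r;
  size_t i = 0;
  int sgn = 1;
  if (i < str.size() && (str[i] == '-' || str[i] == '+')) { if (str[i] == '-') sgn = -1; ++i; }
  if (i >= str.size()) throw std::runtime_error("bad integer literal");
  for (; i < str.size(); ++i) {
    if (str[i] < '0' || str[i] > '9') throw std::runtime_error("bad integer literal");
    r = mul_small(r, 10);
    if (r.is0()) { r = BI(str[i] - '0'); }
    else { r = add(r, BI(str[i] - '0')); }
    if (!r.is0()) r.s = 1;
  }
  if (!r.is0()) r.s = sgn;
  return r;
}

inline std::string to_dec(const BI& a) {
  if (a.is0()) return "0";
  BI x = a; x.s = 1;
  std::string out;
  while (!x.is0()) {
    BI q;
    uint32_t rem = divmod_small(x, 1000000000u, q);
    x = q; x.trim();
    char buf[16];
    if (x.is0()) snprintf(buf, sizeof buf, "%u", rem);
    else snprintf(buf, sizeof buf, "%09u", rem);
    out = std::string(buf) + out;
  }
  return a.s < 0 ? "-" + out : out;
}

inline double to_double(const BI& a) {
  double r = 0;
  for (size_t i = a.d.size(); i-- > 0;) r = r * 4294967296.0 + a.d[i];
  return a.s < 0 ? -r : r;
}

inline long long mod_small(const BI& a, long long p) {
  long long r = 0;
  for (size_t i = a.d.size(); i-- > 0;) r = (long long)(((__int128)r << 32 | a.d[i]) % p);
  if (a.s < 0 && r != 0) r = p - r;
  return r;
}

// ---- rationals ----
struct Rat {
  BI n, d;   // d > 0, gcd(n,d)=1; n.s carries sign
  Rat() : n(0), d(1) {}
  Rat(const BI& nn, const BI& dd) : n(nn), d(dd) { norm(); }
  Rat(long long v) : n(v), d(1) {}
  void norm() {
    if (d.is0()) throw std::runtime_error("zero denominator");
    if (n.is0()) { d = BI(1); return; }
    if (d.s < 0) { n.s = -n.s; d.s = 1; }
    BI g = gcd(n, d);
    if (!is1(g)) {
      BI q, r;
      divmod(n, g, q, r); n = q;
      divmod(d, g, q, r); d = q;
    }
  }
  bool is0() const { return n.is0(); }
};

inline Rat radd(const Rat& a, const Rat& b) { return Rat(add(mul(a.n, b.d), mul(b.n, a.d)), mul(a.d, b.d)); }
inline Rat rsub(const Rat& a, const Rat& b) { return Rat(sub(mul(a.n, b.d), mul(b.n, a.d)), mul(a.d, b.d)); }
inline Rat rmul(const Rat& a, const Rat& b) { return Rat(mul(a.n, b.n), mul(a.d, b.d)); }
inline Rat rdiv(const Rat& a, const Rat& b) {
  if (b.is0()) throw std::runtime_error("rational division by zero");
  return Rat(mul(a.n, b.d), mul(a.d, b.n));
}
inline Rat rneg(const Rat& a) { Rat r = a; r.n.s = -r.n.s; return r; }

inline Rat rat_from_str(const std::string& str) {
  size_t slash = str.find('/');
  if (slash == std::string::npos) return Rat(from_dec(str), BI(1));
  return Rat(from_dec(str.substr(0, slash)), from_dec(str.substr(slash + 1)));
}

inline std::string rat_to_str(const Rat& a) {
  if (is1(a.d)) return to_dec(a.n);
  return to_dec(a.n) + "/" + to_dec(a.d);
}

} // namespace icb
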