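// Arbitrary-precision signed integers (base 2^32) and exact rationals.
// Only the operations needed for sparse rational elimination are provided:
// add/sub/mul, divmod (binary long division), gcd, decimal I/O.
#pragma once

#include <vector>
#include <cstdint>
#include <string>
#include <cmath>
#include <stdexcept>
#include <algorithm>

struct BigInt {
    int sign = 0;              // -1, 0, +1
    std::vector<uint32_t> d;   // little-endian limbs, base 2^32, no leading zeros

    bool isZero() const { return sign == 0; }

    void normalize() {
        while (!d.empty() && d.back() == 0) d.pop_back();
        if (d.empty()) sign = 0;
        else if (sign == 0) sign = 1;
    }

    static BigInt fromInt64(long long v) {
        BigInt r;
        if (v == 0) return r;
        r.sign = v < 0 ? -1 : 1;
        unsigned long long m = v < 0 ? -(unsigned long long)v : (unsigned long long)v;
        while (m) { r.d.push_back((uint32_t)(m & 0xffffffffu)); m >>= 32; }
        return r;
    }

    size_t bitlen() const {
        if (isZero()) return 0;
        uint32_t top = d.back();
        size_t b = (d.size() - 1) * 32;
        while (top) { ++b; top >>= 1; }
        return b;
    }
};

// compare |a| vs |b|
inline int cmpAbs(const BigInt& a, const BigInt& b) {
    if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
    for (size_t k = a.d.size(); k-- > 0;) {
        if (a.d[k] != b.d[k]) return a.d[k] < b.d[k] ? -1 : 1;
    }
    return 0;
}

inline BigInt addAbs(const BigInt& a, const BigInt& b) {
    BigInt r; r.sign = 1;
    size_t n = std::max(a.d.size(), b.d.size());
    r.d.resize(n + 1, 0);
    uint64_t carry = 0;
    for (size_t k = 0; k < n; ++k) {
        uint64_t s = carry;
        if (k < a.d.size()) s += a.d[k];
        if (k < b.d.size()) s += b.d[k];
        r.d[k] = (uint32_t)(s & 0xffffffffu);
        carry = s >> 32;
    }
    r.d[n] = (uint32_t)carry;
    r.normalize();
    return r;
}

// |a| - |b|, requires |a| >= |b|
inline BigInt subAbs(const BigInt& a, const BigInt& b) {
    BigInt r; r.sign = 1;
    r.d.resize(a.d.size(), 0);
    int64_t borrow = 0;
    for (size_t k = 0; k < a.d.size(); ++k) {
        int64_t s = (int64_t)a.d[k] - borrow - (k < b.d.size() ? (int64_t)b.d[k] : 0);
        if (s < 0) { s += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
        r.d[k] = (uint32_t)s;
    }
    r.normalize();
    return r;
}

inline BigInt bigAdd(const BigInt& a, const BigInt& b) {
    if (a.isZero()) return b;
    if (b.isZero()) return a;
    if (a.sign == b.sign) { BigInt r = addAbs(a, b); r.sign = a.sign; r.normalize(); return r; }
    int c = cmpAbs(a, b);
    if (c == 0) return BigInt();
    BigInt r = c > 0 ? subAbs(a, b) : subAbs(b, a);
    r.sign = c > 0 ? a.sign : b.sign;
    r.normalize();
    return r;
}

inline BigInt bigNeg(BigInt a) { a.sign = -a.sign; return a; }

inline BigInt bigSub(const BigInt& a, const BigInt& b) { return bigAdd(a, bigNeg(b)); }

inline BigInt bigMul(const BigInt& a, const BigInt& b) {
    BigInt r;
    if (a.isZero() || b.isZero()) return r;
    r.sign = a.sign * b.sign;
    r.d.assign(a.d.size() + b.d.size(), 0);
    for (size_t i = 0; i < a.d.size(); ++i) {
        uint64_t carry = 0;
        uint64_t av = a.d[i];
        for (size_t j = 0; j < b.d.size(); ++j) {
            uint64_t cur = (uint64_t)r.d[i + j] + av * b.d[j] + carry;
            r.d[i + j] = (uint32_t)(cur & 0xffffffffu);
            carry = cur >> 32;
        }
        size_t k = i + b.d.size();
        while (carry) {
            uint64_t cur = (uint64_t)r.d[k] + carry;
            r.d[k] = (uint32_t)(cur & 0xffffffffu);
            carry = cur >> 32;
            ++k;
        }
    }
    r.normalize();
    return r;
}

inline BigInt shlBits(const BigInt& a, size_t k) {
    if (a.isZero() || k == 0) return a;
    size_t words = k / 32, bits = k % 32;
    BigInt r; r.sign = a.sign;
    r.d.assign(a.d.size() + words + 1, 0);
    for (size_t i = 0; i < a.d.size(); ++i) {
        uint64_t v = (uint64_t)a.d[i] << bits;
        r.d[i + words] |= (uint32_t)(v & 0xffffffffu);
        r.d[i + words + 1] |= (uint32_t)(v >> 32);
    }
    r.normalize();
    return r;
}

inline void shr1(BigInt& a) {
    if (a.isZero()) return;
    uint32_t carry = 0;
    for (size_t k = a.d.size(); k-- > 0;) {
        uint32_t nc = a.d[k] & 1u;
        a.d[k] = (a.d[k] >> 1) | (carry << 31);
        carry = nc;
    }
    a.normalize();
}

// magnitude division: q = floor(|a|/|b|), r = |a| mod |b| (signs of outputs are +)
inline void divmodAbs(const BigInt& a, const BigInt& b, BigInt& q, BigInt& r) {
    if (b.isZero()) throw std::runtime_error("division by zero");
    q = BigInt(); r = a; r.sign = r.isZero() ? 0 : 1;
    if (a.isZero() || cmpAbs(a, b) < 0) return;
    size_t shift = a.bitlen() - b.bitlen();
    BigInt t = shlBits(b, shift); t.sign = 1;
    std::vector<uint32_t> qbits(shift / 32 + 1, 0);
    for (size_t k = shift + 1; k-- > 0;) {
        if (!r.isZero() && cmpAbs(r, t) >= 0) {
            r = subAbs(r, t);
            qbits[k / 32] |= (1u << (k % 32));
        }
        shr1(t);
    }
    q.d = qbits; q.sign = 1; q.normalize();
    r.normalize();
}

inline BigInt gcdAbs(BigInt a, BigInt b) {
    a.sign = a.isZero() ? 0 : 1;
    b.sign = b.isZero() ? 0 : 1;
    while (!b.isZero()) {
        BigInt q, r;
        divmodAbs(a, b, q, r);
        a = b; b = r;
    }
    return a; // zero iff both zero
}

// exact |a|/|b| with sign sign(a)*sign(b); remainder must be zero
inline BigInt divExact(const BigInt& a, const BigInt& b) {
    BigInt q, r;
    divmodAbs(a, b, q, r);
    q.sign = q.isZero() ? 0 : a.sign * b.sign;
    return q;
}

inline uint32_t divmodSmall(BigInt& a, uint32_t dvr) {
    uint64_t rem = 0;
    for (size_t k = a.d.size(); k-- > 0;) {
        uint64_t cur = (rem << 32) | a.d[k];
        a.d[k] = (uint32_t)(cur / dvr);
        rem = cur % dvr;
    }
    a.normalize();
    return (uint32_t)rem;
}

inline void mulSmallAdd(BigInt& a, uint32_t m, uint32_t add) {
    uint64_t carry = add;
    for (size_t k = 0; k < a.d.size(); ++k) {
        uint64_t cur = (uint64_t)a.d[k] * m + carry;
        a.d[k] = (uint32_t)(cur & 0xffffffffu);
        carry = cur >> 32;
    }
    while (carry) { a.d.push_back((uint32_t)(carry & 0xffffffffu)); carry >>= 32; }
    a.normalize();
    if (!a.isZero() && a.sign == 0) a.sign = 1;
}

inline BigInt bigFromDecimal(const std::string& s, size_t lo, size_t hi) {
    BigInt r; r.sign = 1; r.d.clear();
    for (size_t k = lo; k < hi; ++k) {
        char c = s[k];
        if (c < '0' || c > '9') throw std::runtime_error("invalid integer literal: " + s);
        mulSmallAdd(r, 10u, (uint32_t)(c - '0'));
    }
    r.normalize();
    return r;
}

inline std::string bigToString(const BigInt& a) {
    if (a.isZero()) return "0";
    BigInt t = a; t.sign = 1;
    std::string out;
    while (!t.isZero()) {
        uint32_t rem = divmodSmall(t, 1000000000u);
        for (int k = 0; k < 9; ++k) {
            out.push_back((char)('0' + rem % 10));
            rem /= 10;
        }
    }
    while (out.size() > 1 && out.back() == '0') out.pop_back();
    if (a.sign < 0) out.push_back('-');
    std::reverse(out.begin(), out.end());
    return out;
}

inline double bigToDouble(const BigInt& a) {
    if (a.isZero()) return 0.0;
    // top <= 64 bits as mantissa, scaled by remaining bit length
    size_t bl = a.bitlen();
    uint64_t m = 0;
    int take = (int)std::min<size_t>(bl, 64);
    for (int k = 0; k < take; ++k) {
        size_t bit = bl - 1 - k;
        uint32_t limb = a.d[bit / 32];
        int b = (int)(bit % 32);
        m = (m << 1) | ((limb >> b) & 1u);
    }
    double v = std::ldexp((double)m, (int)(bl - take));
    return a.sign < 0 ? -v : v;
}

inline BigInt pow10Big(size_t k) {
    BigInt r = BigInt::fromInt64(1);
    for (size_t i = 0; i < k; ++i) mulSmallAdd(r, 10u, 0u);
    return r;
}

// ---------------------------------------------------------------------------

struct Rat {
    BigInt n;  // carries the sign
    BigInt d;  // always positive

    Rat() : n(), d(BigInt::fromInt64(1)) {}

    static Rat make(BigInt nn, BigInt dd) {
        if (dd.isZero()) throw std::runtime_error("rational with zero denominator");
        Rat r;
        if (nn.isZero()) { r.n = BigInt(); r.d = BigInt::fromInt64(1); return r; }
        int s = nn.sign * dd.sign;
        nn.sign = 1; dd.sign = 1;
        BigInt g = gcdAbs(nn, dd);
        r.n = divExact(nn, g);
        r.d = divExact(dd, g);
        r.n.sign = s;
        return r;
    }

    static Rat fromInt(long long v) { Rat r; r.n = BigInt::fromInt64(v); return r; }

    bool isZero() const { return n.isZero(); }
    bool isOne() const {
        return n.sign == 1 && n.d.size() == 1 && n.d[0] == 1 && d.d.size() == 1 && d.d[0] == 1;
    }
};

inline Rat ratAdd(const Rat& a, const Rat& b) {
    return Rat::make(bigAdd(bigMul(a.n, b.d), bigMul(b.n, a.d)), bigMul(a.d, b.d));
}
inline Rat ratSub(const Rat& a, const Rat& b) {
    return Rat::make(bigSub(bigMul(a.n, b.d), bigMul(b.n, a.d)), bigMul(a.d, b.d));
}
inline Rat ratMul(const Rat& a, const Rat& b) {
    return Rat::make(bigMul(a.n, b.n), bigMul(a.d, b.d));
}
inline Rat ratDiv(const Rat& a, const Rat& b) {
    if (b.isZero()) throw std::runtime_error("rational division by zero");
    return Rat::make(bigMul(a.n, b.d), bigMul(a.d, b.n));
}
inline Rat ratNeg(Rat a) { a.n.sign = -a.n.sign; return a; }
inline Rat ratInv(const Rat& a) { return ratDiv(Rat::fromInt(1), a); }

inline int ratCmp(const Rat& a, const Rat& b) {
    BigInt diff = bigSub(bigMul(a.n, b.d), bigMul(b.n, a.d));
    return diff.sign;
}

inline double ratToDouble(const Rat& a) {
    if (a.isZero()) return 0.0;
    return bigToDouble(a.n) / bigToDouble(a.d);
}

inline size_t ratBits(const Rat& a) { return std::max(a.n.bitlen(), a.d.bitlen()); }

inline std::string ratToString(const Rat& a) {
    std::string s = bigToString(a.n);
    if (!(a.d.d.size() == 1 && a.d.d[0] == 1)) {
        s += "/";
        s += bigToString(a.d);
    }
    return s;
}

// Accepts "p", "-p", "p/q", decimal literals ("0.5", "-1.25e-3").
// Decimal text is converted exactly: "0.1" becomes 1/10.
inline Rat ratParse(const std::string& s0) {
    std::string s;
    for (char c : s0) if (!std::isspace((unsigned char)c)) s.push_back(c);
    if (s.empty()) throw std::runtime_error("empty rational literal");
    size_t slash = s.find('/');
    if (slash != std::string::npos) {
        std::string p = s.substr(0, slash), q = s.substr(slash + 1);
        int sp = 1, sq = 1; size_t ip = 0, iq = 0;
        if (!p.empty() && (p[0] == '-' || p[0] == '+')) { if (p[0] == '-') sp = -1; ip = 1; }
        if (!q.empty() && (q[0] == '-' || q[0] == '+')) { if (q[0] == '-') sq = -1; iq = 1; }
        BigInt np = bigFromDecimal(p, ip, p.size());
        BigInt nq = bigFromDecimal(q, iq, q.size());
        np.sign = np.isZero() ? 0 : sp;
        nq.sign = nq.isZero() ? 0 : sq;
        return Rat::make(np, nq);
    }
    int sign = 1; size_t pos = 0;
    if (s[0] == '-' || s[0] == '+') { if (s[0] == '-') sign = -1; pos = 1; }
    std::string digits;
    long long exp10 = 0;
    bool seenDot = false, any = false;
    for (; pos < s.size(); ++pos) {
        char c = s[pos];
        if (c >= '0' && c <= '9') {
            digits.push_back(c);
            if (seenDot) --exp10;
            any = true;
        } else if (c == '.') {
            if (seenDot) throw std::runtime_error("invalid numeric literal: " + s0);
            seenDot = true;
        } else if (c == 'e' || c == 'E') {
            ++pos;
            int es = 1; long long ev = 0; bool edig = false;
            if (pos < s.size() && (s[pos] == '-' || s[pos] == '+')) { if (s[pos] == '-') es = -1; ++pos; }
            for (; pos < s.size(); ++pos) {
                if (s[pos] < '0' || s[pos] > '9') throw std::runtime_error("invalid exponent: " + s0);
                ev = ev * 10 + (s[pos] - '0');
                edig = true;
            }
            if (!edig) throw std::runtime_error("invalid exponent: " + s0);
            exp10 += es * ev;
            break;
        } else {
            throw std::runtime_error("invalid numeric literal: " + s0);
        }
    }
    if (!any) throw std::runtime_error("invalid numeric literal: " + s0);
    BigInt num = bigFromDecimal(digits, 0, digits.size());
    num.sign = num.isZero() ? 0 : sign;
    BigInt den = BigInt::fromInt64(1);
    if (exp10 > 0) num = bigMul(num, pow10Big((size_t)exp10));
    else if (exp10 < 0) den = pow10Big((size_t)(-exp10));
    return Rat::make(num, den);
}
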