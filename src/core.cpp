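// Sparse exact-rational kernels: Gauss-Jordan elimination with a
// Markowitz-style pivot rule, row-operation replay, exact sparse products,
// and a deliberately naive dense eliminator used as an internal cross-check.
#include <Rcpp.h>
#include <map>
#include "bigrat.h"

using namespace Rcpp;

typedef std::map<int, Rat> SparseRow;   // col (0-based) -> nonzero value

static std::vector<SparseRow> buildRows(int nrow, int ncol,
                                        const IntegerVector& ri,
                                        const IntegerVector& rj,
                                        const CharacterVector& val) {
    if (ri.size() != rj.size() || ri.size() != val.size())
        stop("triplet vectors must have equal length");
    std::vector<SparseRow> rows((size_t)nrow);
    for (R_xlen_t k = 0; k < ri.size(); ++k) {
        int i = ri[k] - 1, j = rj[k] - 1;
        if (i < 0 || i >= nrow || j < 0 || j >= ncol)
            stop("triplet index out of bounds");
        Rat v = ratParse(as<std::string>(val[k]));
        if (v.isZero()) continue;
        if (rows[i].count(j)) stop("duplicate triplet entry");
        rows[i][j] = v;
    }
    return rows;
}

static List emitRows(const std::vector<SparseRow>& rows, int nrow, int ncol) {
    std::vector<int> oi, oj;
    std::vector<std::string> ov;
    for (int i = 0; i < nrow; ++i) {
        for (auto const& kv : rows[(size_t)i]) {
            oi.push_back(i + 1);
            oj.push_back(kv.first + 1);
            ov.push_back(ratToString(kv.second));
        }
    }
    return List::create(_["nrow"] = nrow, _["ncol"] = ncol,
                        _["i"] = wrap(oi), _["j"] = wrap(oj), _["val"] = wrap(ov));
}

// ---------------------------------------------------------------------------
// scalar rational utilities (vectorised over character vectors)

// [[Rcpp::export]]
CharacterVector cpp_rat_norm(CharacterVector x) {
    CharacterVector out(x.size());
    for (R_xlen_t k = 0; k < x.size(); ++k) {
        if (CharacterVector::is_na(x[k])) { out[k] = NA_STRING; continue; }
        out[k] = ratToString(ratParse(as<std::string>(x[k])));
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_rat_arith(CharacterVector a, CharacterVector b, std::string op) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (n == 0) return CharacterVector(0);
    if (a.size() == 0 || b.size() == 0) stop("zero-length operand");
    CharacterVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        Rat x = ratParse(as<std::string>(a[k % a.size()]));
        Rat y = ratParse(as<std::string>(b[k % b.size()]));
        Rat r;
        if (op == "+") r = ratAdd(x, y);
        else if (op == "-") r = ratSub(x, y);
        else if (op == "*") r = ratMul(x, y);
        else if (op == "/") r = ratDiv(x, y);
        else stop("unknown op: %s", op.c_str());
        out[k] = ratToString(r);
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rat_cmp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (a.size() == 0 || b.size() == 0) stop("zero-length operand");
    IntegerVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        Rat x = ratParse(as<std::string>(a[k % a.size()]));
        Rat y = ratParse(as<std::string>(b[k % b.size()]));
        out[k] = ratCmp(x, y);
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_rat_to_double(CharacterVector x) {
    NumericVector out(x.size());
    for (R_xlen_t k = 0; k < x.size(); ++k) {
        if (CharacterVector::is_na(x[k])) { out[k] = NA_REAL; continue; }
        out[k] = ratToDouble(ratParse(as<std::string>(x[k])));
    }
    return out;
}

// Exact terminating-decimal rendering; NA where the expansion does not
// terminate (denominator has a prime factor other than 2 or 5).
// [[Rcpp::export]]
CharacterVector cpp_rat_decimal(CharacterVector x) {
    CharacterVector out(x.size());
    for (R_xlen_t k = 0; k < x.size(); ++k) {
        if (CharacterVector::is_na(x[k])) { out[k] = NA_STRING; continue; }
        Rat r = ratParse(as<std::string>(x[k]));
        BigInt den = r.d;
        int twos = 0, fives = 0;
        for (;;) {
            BigInt t = den;
            if (divmodSmall(t, 2u) == 0 && !den.isZero() && !(den.d.size() == 1 && den.d[0] == 1)) { den = t; ++twos; }
            else break;
        }
        for (;;) {
            BigInt t = den;
            if (divmodSmall(t, 5u) == 0 && !(den.d.size() == 1 && den.d[0] == 1)) { den = t; ++fives; }
            else break;
        }
        if (!(den.d.size() == 1 && den.d[0] == 1)) { out[k] = NA_STRING; continue; }
        int digits = std::max(twos, fives);
        BigInt num = r.n; num.sign = 1;
        // scale numerator to an integer over 10^digits
        for (int t = 0; t < digits - twos; ++t) mulSmallAdd(num, 2u, 0u);
        for (int t = 0; t < digits - fives; ++t) mulSmallAdd(num, 5u, 0u);
        std::string s = bigToString(num);
        if (digits > 0) {
            while ((int)s.size() <= digits) s = "0" + s;
            s.insert(s.size() - digits, ".");
        }
        if (r.n.sign < 0) s = "-" + s;
        out[k] = s;
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rat_bits(CharacterVector x) {
    IntegerVector out(x.size());
    for (R_xlen_t k = 0; k < x.size(); ++k)
        out[k] = (int)ratBits(ratParse(as<std::string>(x[k])));
    return out;
}

// ---------------------------------------------------------------------------
// row-operation log shared by elimination and replay

struct OpLog {
    std::vector<int> kind;      // 0 swap, 1 scale, 2 add_multiple
    std::vector<int> target;    // 1-based
    std::vector<int> source;    // 1-based or NA
    std::vector<std::string> factor;
    void swapOp(int t, int s) {
        kind.push_back(0); target.push_back(t + 1); source.push_back(s + 1);
        factor.push_back("");
    }
    void scaleOp(int t, const Rat& f) {
        kind.push_back(1); target.push_back(t + 1); source.push_back(NA_INTEGER);
        factor.push_back(ratToString(f));
    }
    void addOp(int t, int s, const Rat& f) {
        kind.push_back(2); target.push_back(t + 1); source.push_back(s + 1);
        factor.push_back(ratToString(f));
    }
};

static size_t rowMaxBits(const SparseRow& r) {
    size_t b = 0;
    for (auto const& kv : r) b = std::max(b, ratBits(kv.second));
    return b;
}

// target += f * source (sparse)
static void axpyRow(SparseRow& tgt, const SparseRow& src, const Rat& f) {
    for (auto const& kv : src) {
        Rat add = ratMul(f, kv.second);
        auto it = tgt.find(kv.first);
        if (it == tgt.end()) {
            if (!add.isZero()) tgt[kv.first] = add;
        } else {
            Rat s = ratAdd(it->second, add);
            if (s.isZero()) tgt.erase(it);
            else it->second = s;
        }
    }
}

static void scaleRow(SparseRow& r, const Rat& f) {
    for (auto& kv : r) kv.second = ratMul(kv.second, f);
}

// ---------------------------------------------------------------------------
// Gauss-Jordan elimination.
//
// Pivot rule: preferred columns are tried first, in preference order; after
// that a Markowitz criterion picks the admissible nonzero minimising
// (row nnz - 1) * (col nnz - 1), ties broken by smallest column then row
// index. Columns in `forbidden` (requested independent fluxes) are used only
// when no other column can complete the reduction; such moves are reported.

// [[Rcpp::export]]
List cpp_gje(int nrow, int ncol, IntegerVector ri, IntegerVector rj,
             CharacterVector val, IntegerVector preferred, IntegerVector forbidden) {
    std::vector<SparseRow> rows = buildRows(nrow, ncol, ri, rj, val);
    std::vector<bool> colUsed((size_t)ncol, false);
    std::vector<bool> isForbidden((size_t)ncol, false);
    std::vector<int> rowPivotCol((size_t)nrow, -1);
    for (R_xlen_t k = 0; k < forbidden.size(); ++k) {
        int c = forbidden[k] - 1;
        if (c < 0 || c >= ncol) stop("forbidden pivot column out of range");
        isForbidden[(size_t)c] = true;
    }
    std::vector<int> pref;
    for (R_xlen_t k = 0; k < preferred.size(); ++k) {
        int c = preferred[k] - 1;
        if (c < 0 || c >= ncol) stop("preferred dependent column out of range");
        if (isForbidden[(size_t)c]) stop("column cannot be both preferred-dependent and forbidden");
        pref.push_back(c);
    }

    OpLog log;
    std::vector<int> movedCols;
    size_t maxBits = 0;
    for (int i = 0; i < nrow; ++i) maxBits = std::max(maxBits, rowMaxBits(rows[(size_t)i]));

    for (;;) {
        // active counts over unpivoted rows
        std::vector<int> colCount((size_t)ncol, 0);
        std::vector<int> rowCount((size_t)nrow, 0);
        bool anyActive = false;
        for (int i = 0; i < nrow; ++i) {
            if (rowPivotCol[(size_t)i] >= 0) continue;
            for (auto const& kv : rows[(size_t)i]) {
                ++colCount[(size_t)kv.first];
                ++rowCount[(size_t)i];
                anyActive = true;
            }
        }
        if (!anyActive) break;

        int pcol = -1, prow = -1;
        // 1. preferred columns, in preference order
        for (int c : pref) {
            if (colUsed[(size_t)c] || colCount[(size_t)c] == 0) continue;
            int best = -1;
            for (int i = 0; i < nrow; ++i) {
                if (rowPivotCol[(size_t)i] >= 0) continue;
                if (!rows[(size_t)i].count(c)) continue;
                if (best < 0 || rowCount[(size_t)i] < rowCount[(size_t)best]) best = i;
            }
            pcol = c; prow = best;
            break;
        }
        // 2. Markowitz over admissible columns
        if (pcol < 0) {
            long long bestScore = -1;
            for (int i = 0; i < nrow; ++i) {
                if (rowPivotCol[(size_t)i] >= 0) continue;
                for (auto const& kv : rows[(size_t)i]) {
                    int c = kv.first;
                    if (colUsed[(size_t)c] || isForbidden[(size_t)c]) continue;
                    long long score = (long long)(rowCount[(size_t)i] - 1) *
                                      (long long)(colCount[(size_t)c] - 1);
                    if (bestScore < 0 || score < bestScore ||
                        (score == bestScore && (c < pcol || (c == pcol && i < prow)))) {
                        bestScore = score; pcol = c; prow = i;
                    }
                }
            }
        }
        // 3. fallback: a requested independent column must become dependent
        if (pcol < 0) {
            long long bestScore = -1;
            for (int i = 0; i < nrow; ++i) {
                if (rowPivotCol[(size_t)i] >= 0) continue;
                for (auto const& kv : rows[(size_t)i]) {
                    int c = kv.first;
                    if (colUsed[(size_t)c]) continue;
                    long long score = (long long)(rowCount[(size_t)i] - 1) *
                                      (long long)(colCount[(size_t)c] - 1);
                    if (bestScore < 0 || score < bestScore ||
                        (score == bestScore && (c < pcol || (c == pcol && i < prow)))) {
                        bestScore = score; pcol = c; prow = i;
                    }
                }
            }
            if (pcol < 0) break;
            movedCols.push_back(pcol + 1);
        }

        SparseRow& pr = rows[(size_t)prow];
        Rat pv = pr[pcol];
        if (!pv.isOne()) {
            Rat inv = ratInv(pv);
            log.scaleOp(prow, inv);
            scaleRow(pr, inv);
            maxBits = std::max(maxBits, rowMaxBits(pr));
        }
        for (int i = 0; i < nrow; ++i) {
            if (i == prow) continue;
            auto it = rows[(size_t)i].find(pcol);
            if (it == rows[(size_t)i].end()) continue;
            Rat f = ratNeg(it->second);
            log.addOp(i, prow, f);
            axpyRow(rows[(size_t)i], pr, f);
            maxBits = std::max(maxBits, rowMaxBits(rows[(size_t)i]));
        }
        rowPivotCol[(size_t)prow] = pcol;
        colUsed[(size_t)pcol] = true;
    }

    // reorder: pivot rows first, sorted by pivot column; record as swaps
    std::vector<std::pair<int,int>> pivots; // (col, row)
    for (int i = 0; i < nrow; ++i)
        if (rowPivotCol[(size_t)i] >= 0) pivots.push_back({rowPivotCol[(size_t)i], i});
    std::sort(pivots.begin(), pivots.end());
    std::vector<int> desired; // current row indices in desired final order
    std::vector<bool> taken((size_t)nrow, false);
    for (auto const& pc : pivots) { desired.push_back(pc.second); taken[(size_t)pc.second] = true; }
    for (int i = 0; i < nrow; ++i) if (!taken[(size_t)i]) desired.push_back(i);
    // realise permutation with swaps; track where each original row now lives
    std::vector<int> pos((size_t)nrow);   // pos[orig] = current index
    std::vector<int> at((size_t)nrow);    // at[index] = orig row
    for (int i = 0; i < nrow; ++i) { pos[(size_t)i] = i; at[(size_t)i] = i; }
    for (int k = 0; k < nrow; ++k) {
        int want = desired[(size_t)k];
        int cur = pos[(size_t)want];
        if (cur == k) continue;
        log.swapOp(k, cur);
        std::swap(rows[(size_t)k], rows[(size_t)cur]);
        int other = at[(size_t)k];
        std::swap(at[(size_t)k], at[(size_t)cur]);
        pos[(size_t)want] = k;
        pos[(size_t)other] = cur;
    }

    std::vector<int> pivotCols, freeCols;
    for (auto const& pc : pivots) pivotCols.push_back(pc.first + 1);
    std::vector<bool> isPivot((size_t)ncol, false);
    for (auto const& pc : pivots) isPivot[(size_t)pc.first] = true;
    for (int c = 0; c < ncol; ++c) if (!isPivot[(size_t)c]) freeCols.push_back(c + 1);

    IntegerVector src(log.source.size());
    for (size_t k = 0; k < log.source.size(); ++k) src[k] = log.source[k];
    CharacterVector fac(log.factor.size());
    for (size_t k = 0; k < log.factor.size(); ++k)
        fac[k] = log.kind[k] == 0 ? NA_STRING : String(log.factor[k]);

    return List::create(
        _["echelon"] = emitRows(rows, nrow, ncol),
        _["pivot_columns"] = wrap(pivotCols),
        _["free_columns"] = wrap(freeCols),
        _["rank"] = (int)pivots.size(),
        _["ops_kind"] = wrap(log.kind),
        _["ops_target"] = wrap(log.target),
        _["ops_source"] = src,
        _["ops_factor"] = fac,
        _["moved_to_dependent"] = wrap(movedCols),
        _["max_bits"] = (int)maxBits);
}

// [[Rcpp::export]]
List cpp_replay(IntegerVector kind, IntegerVector target, IntegerVector source,
                CharacterVector factor, int nrow, int ncol,
                IntegerVector ri, IntegerVector rj, CharacterVector val) {
    std::vector<SparseRow> rows = buildRows(nrow, ncol, ri, rj, val);
    if (kind.size() != target.size() || kind.size() != source.size() ||
        kind.size() != factor.size())
        stop("row-operation log columns must have equal length");
    for (R_xlen_t k = 0; k < kind.size(); ++k) {
        int t = target[k] - 1;
        if (t < 0 || t >= nrow) stop("row operation target out of range");
        if (kind[k] == 0) {
            int s = source[k] - 1;
            if (s < 0 || s >= nrow) stop("row operation source out of range");
            std::swap(rows[(size_t)t], rows[(size_t)s]);
        } else if (kind[k] == 1) {
            Rat f = ratParse(as<std::string>(factor[k]));
            if (f.isZero()) stop("scale factor must be nonzero");
            scaleRow(rows[(size_t)t], f);
        } else if (kind[k] == 2) {
            int s = source[k] - 1;
            if (s < 0 || s >= nrow) stop("row operation source out of range");
            Rat f = ratParse(as<std::string>(factor[k]));
            axpyRow(rows[(size_t)t], rows[(size_t)s], f);
        } else {
            stop("unknown row operation kind");
        }
    }
    return emitRows(rows, nrow, ncol);
}

// [[Rcpp::export]]
List cpp_mat_mult(int an, int am, IntegerVector ai, IntegerVector aj, CharacterVector av,
                  int bn, int bm, IntegerVector bi, IntegerVector bj, CharacterVector bv) {
    if (am != bn) stop("non-conformable matrices: %d x %d times %d x %d", an, am, bn, bm);
    std::vector<SparseRow> A = buildRows(an, am, ai, aj, av);
    std::vector<SparseRow> B = buildRows(bn, bm, bi, bj, bv);
    std::vector<SparseRow> C((size_t)an);
    for (int i = 0; i < an; ++i) {
        for (auto const& ka : A[(size_t)i]) {
            const SparseRow& brow = B[(size_t)ka.first];
            for (auto const& kb : brow) {
                Rat add = ratMul(ka.second, kb.second);
                auto it = C[(size_t)i].find(kb.first);
                if (it == C[(size_t)i].end()) {
                    if (!add.isZero()) C[(size_t)i][kb.first] = add;
                } else {
                    Rat s = ratAdd(it->second, add);
                    if (s.isZero()) C[(size_t)i].erase(it);
                    else it->second = s;
                }
            }
        }
    }
    return emitRows(C, an, bm);
}

// ---------------------------------------------------------------------------
// Naive dense reduced-row-echelon oracle. No sparsity bookkeeping, no pivot
// scoring: pivots are taken in the supplied column order (or left to right),
// within a column the first unused row wins. Kept deliberately simple and
// separate from cpp_gje so the two can check each other.

// [[Rcpp::export]]
List cpp_dense_rref(int nrow, int ncol, IntegerVector ri, IntegerVector rj,
                    CharacterVector val, IntegerVector pivot_col_order) {
    std::vector<std::vector<Rat>> m((size_t)nrow, std::vector<Rat>((size_t)ncol));
    for (R_xlen_t k = 0; k < ri.size(); ++k) {
        int i = ri[k] - 1, j = rj[k] - 1;
        if (i < 0 || i >= nrow || j < 0 || j >= ncol) stop("index out of bounds");
        m[(size_t)i][(size_t)j] = ratParse(as<std::string>(val[k]));
    }
    std::vector<int> order;
    if (pivot_col_order.size() > 0) {
        for (R_xlen_t k = 0; k < pivot_col_order.size(); ++k) {
            int c = pivot_col_order[k] - 1;
            if (c < 0 || c >= ncol) stop("pivot column out of range");
            order.push_back(c);
        }
    } else {
        for (int c = 0; c < ncol; ++c) order.push_back(c);
    }
    std::vector<bool> rowUsed((size_t)nrow, false);
    std::vector<std::pair<int,int>> pivots; // (col, row)
    for (int c : order) {
        int prow = -1;
        for (int i = 0; i < nrow; ++i) {
            if (!rowUsed[(size_t)i] && !m[(size_t)i][(size_t)c].isZero()) { prow = i; break; }
        }
        if (prow < 0) continue;
        Rat inv = ratInv(m[(size_t)prow][(size_t)c]);
        for (int j = 0; j < ncol; ++j)
            m[(size_t)prow][(size_t)j] = ratMul(m[(size_t)prow][(size_t)j], inv);
        for (int i = 0; i < nrow; ++i) {
            if (i == prow || m[(size_t)i][(size_t)c].isZero()) continue;
            Rat f = ratNeg(m[(size_t)i][(size_t)c]);
            for (int j = 0; j < ncol; ++j)
                m[(size_t)i][(size_t)j] =
                    ratAdd(m[(size_t)i][(size_t)j], ratMul(f, m[(size_t)prow][(size_t)j]));
        }
        rowUsed[(size_t)prow] = true;
        pivots.push_back({c, prow});
    }
    std::sort(pivots.begin(), pivots.end());
    std::vector<std::vector<Rat>> out;
    std::vector<bool> placed((size_t)nrow, false);
    for (auto const& pc : pivots) { out.push_back(m[(size_t)pc.second]); placed[(size_t)pc.second] = true; }
    for (int i = 0; i < nrow; ++i) if (!placed[(size_t)i]) out.push_back(m[(size_t)i]);

    std::vector<int> oi, oj;
    std::vector<std::string> ov;
    for (int i = 0; i < nrow; ++i)
        for (int j = 0; j < ncol; ++j)
            if (!out[(size_t)i][(size_t)j].isZero()) {
                oi.push_back(i + 1); oj.push_back(j + 1);
                ov.push_back(ratToString(out[(size_t)i][(size_t)j]));
            }
    std::vector<int> pivotCols;
    for (auto const& pc : pivots) pivotCols.push_back(pc.first + 1);
    return List::create(
        _["echelon"] = List::create(_["nrow"] = nrow, _["ncol"] = ncol,
                                    _["i"] = wrap(oi), _["j"] = wrap(oj), _["val"] = wrap(ov)),
        _["pivot_columns"] = wrap(pivotCols),
        _["rank"] = (int)pivots.size());
}
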