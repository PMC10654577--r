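#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Unit-cost edit distance, two-row dynamic programme.
static int lev1(const std::string &a, const std::string &b) {
    const int n = a.size(), m = b.size();
    if (n == 0) return m;
    if (m == 0) return n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export]]
IntegerVector lev_pair_cpp(CharacterVector a, CharacterVector b) {
    if (a.size() != b.size()) stop("a and b must have equal length");
    IntegerVector out(a.size());
    for (R_xlen_t i = 0; i < a.size(); ++i)
        out[i] = lev1(as<std::string>(a[i]), as<std::string>(b[i]));
    return out;
}

// [[Rcpp::export]]
IntegerMatrix lev_cross_cpp(CharacterVector a, CharacterVector b) {
    IntegerMatrix out(a.size(), b.size());
    std::vector<std::string> bs(b.size());
    for (R_xlen_t j = 0; j < b.size(); ++j) bs[j] = as<std::string>(b[j]);
    for (R_xlen_t i = 0; i < a.size(); ++i) {
        std::string ai = as<std::string>(a[i]);
        for (R_xlen_t j = 0; j < b.size(); ++j)
            out(i, j) = lev1(ai, bs[j]);
    }
    return out;
}

// Global alignment with affine gaps (Gotoh).  Scores: +match on equal
// bases, +mismatch otherwise; a gap of length k costs gap_open + k*gap_ext.
// Returns the two gapped strings and the score.
// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b,
                   double match = 2.0, double mismatch = -4.0,
                   double gap_open = 4.0, double gap_ext = 2.0) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e18;
    // state 0 = M (diag), 1 = X (gap in b, consume a), 2 = Y (gap in a)
    std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
        Y((n + 1) * (m + 1), NEG);
    std::vector<unsigned char> tbM((n + 1) * (m + 1)), tbX((n + 1) * (m + 1)),
        tbY((n + 1) * (m + 1));
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[at(i, 0)] = -(gap_open + gap_ext * i);
        tbX[at(i, 0)] = 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[at(0, j)] = -(gap_open + gap_ext * j);
        tbY[at(0, j)] = 2;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
                   y0 = Y[at(i - 1, j - 1)];
            double best = m0; unsigned char tb = 0;
            if (x0 > best) { best = x0; tb = 1; }
            if (y0 > best) { best = y0; tb = 2; }
            M[at(i, j)] = best + s; tbM[at(i, j)] = tb;

            double xo = M[at(i - 1, j)] - (gap_open + gap_ext);
            double xe = X[at(i - 1, j)] - gap_ext;
            if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
            else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }

            double yo = M[at(i, j - 1)] - (gap_open + gap_ext);
            double ye = Y[at(i, j - 1)] - gap_ext;
            if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
            else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
        }
    }
    int i = n, j = m, state = 0;
    double sc = M[at(n, m)];
    if (X[at(n, m)] > sc) { sc = X[at(n, m)]; state = 1; }
    if (Y[at(n, m)] > sc) { sc = Y[at(n, m)]; state = 2; }
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    while (i > 0 || j > 0) {
        if (state == 0) {
            unsigned char tb = tbM[at(i, j)];
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j; state = tb;
        } else if (state == 1) {
            unsigned char tb = tbX[at(i, j)];
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i; state = tb;
        } else {
            unsigned char tb = tbY[at(i, j)];
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j; state = tb;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = sc);
}

// Local alignment with affine gaps (Smith-Waterman / Gotoh) and traceback.
// Returns aligned strings, 1-based aligned ranges on both sequences, the
// score and match/mismatch/indel counts of the aligned region.
// [[Rcpp::export]]
List sw_affine_cpp(std::string a, std::string b,
                   double match = 2.0, double mismatch = -4.0,
                   double gap_open = 4.0, double gap_ext = 2.0) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e18;
    std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG),
        Y((n + 1) * (m + 1), NEG);
    std::vector<unsigned char> tbM((n + 1) * (m + 1), 3), tbX((n + 1) * (m + 1)),
        tbY((n + 1) * (m + 1));
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
            double m0 = M[at(i - 1, j - 1)], x0 = X[at(i - 1, j - 1)],
                   y0 = Y[at(i - 1, j - 1)];
            double bd = m0; unsigned char tb = 0;
            if (x0 > bd) { bd = x0; tb = 1; }
            if (y0 > bd) { bd = y0; tb = 2; }
            double v = bd + s;
            if (v < 0.0) { v = 0.0; tb = 3; } // local start
            M[at(i, j)] = v; tbM[at(i, j)] = tb;

            double xo = M[at(i - 1, j)] - (gap_open + gap_ext);
            double xe = X[at(i - 1, j)] - gap_ext;
            if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
            else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
            double yo = M[at(i, j - 1)] - (gap_open + gap_ext);
            double ye = Y[at(i, j - 1)] - gap_ext;
            if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
            else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
            if (v > best) { best = v; bi = i; bj = j; }
        }
    }
    std::string ra, rb;
    int nmatch = 0, nmismatch = 0, nins = 0, ndel = 0;
    int i = bi, j = bj, state = 0;
    while (i > 0 && j > 0) {
        if (state == 0) {
            unsigned char tb = tbM[at(i, j)];
            if (tb == 3 && M[at(i, j)] == 0.0) break;
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            if (a[i - 1] == b[j - 1]) ++nmatch; else ++nmismatch;
            --i; --j;
            if (tb == 3) break;
            state = tb;
        } else if (state == 1) {
            unsigned char tb = tbX[at(i, j)];
            ra.push_back(a[i - 1]); rb.push_back('-');
            ++nins; --i; state = tb;
        } else {
            unsigned char tb = tbY[at(i, j)];
            ra.push_back('-'); rb.push_back(b[j - 1]);
            ++ndel; --j; state = tb;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(
        _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = best,
        _["a_start"] = i + 1, _["a_end"] = bi, _["b_start"] = j + 1,
        _["b_end"] = bj, _["nmatch"] = nmatch, _["nmismatch"] = nmismatch,
        _["nins"] = nins, _["ndel"] = ndel,
        _["columns"] = nmatch + nmismatch + nins + ndel);
}

// Semi-global scan: find non-overlapping occurrences of `pattern` inside
// `text` with edit distance <= max_dist.  The pattern must align end to
// end; start/end inside the text are free.  Greedy best-first selection,
// ties resolved leftmost.  Returns a matrix with columns start, end, dist
// (1-based, inclusive).
// [[Rcpp::export]]
IntegerMatrix adapter_scan_cpp(std::string text, std::string pattern,
                               int max_dist = 4) {
    const int n = text.size(), m = pattern.size();
    if (m == 0 || n == 0) return IntegerMatrix(0, 3);
    // D[j][i]: best distance aligning pattern[1..j] ending at text pos i.
    // S[j][i]: start position (0-based, position after which match begins).
    std::vector<int> Dprev(n + 1), Dcur(n + 1), Sprev(n + 1), Scur(n + 1);
    std::vector<int> endDist(n + 1), endStart(n + 1);
    for (int i = 0; i <= n; ++i) { Dprev[i] = 0; Sprev[i] = i; }
    for (int j = 1; j <= m; ++j) {
        Dcur[0] = j; Scur[0] = 0;
        for (int i = 1; i <= n; ++i) {
            int sub = Dprev[i - 1] + (pattern[j - 1] == text[i - 1] ? 0 : 1);
            int del = Dprev[i] + 1;   // skip pattern base
            int ins = Dcur[i - 1] + 1; // skip text base
            int best = sub, st = Sprev[i - 1];
            if (del < best) { best = del; st = Sprev[i]; }
            if (ins < best) { best = ins; st = Scur[i - 1]; }
            Dcur[i] = best; Scur[i] = st;
        }
        std::swap(Dprev, Dcur); std::swap(Sprev, Scur);
    }
    for (int i = 0; i <= n; ++i) { endDist[i] = Dprev[i]; endStart[i] = Sprev[i]; }
    std::vector<bool> banned(n + 1, false);
    std::vector<std::array<int, 3>> hits;
    while (true) {
        int bi = -1, bd = max_dist + 1;
        for (int i = m > max_dist ? m - max_dist : 1; i <= n; ++i) {
            if (banned[i]) continue;
            if (endDist[i] < bd) { bd = endDist[i]; bi = i; }
        }
        if (bi < 0) break;
        int st = endStart[bi] + 1; // 1-based first text position of match
        hits.push_back({st, bi, bd});
        for (int i = 1; i <= n; ++i) {
            if (banned[i]) continue;
            int s2 = endStart[i] + 1;
            if (!(i < st || s2 > bi)) banned[i] = true; // overlaps chosen hit
        }
    }
    std::sort(hits.begin(), hits.end(),
              [](const std::array<int, 3> &x, const std::array<int, 3> &y) {
                  return x[0] < y[0];
              });
    IntegerMatrix out(hits.size(), 3);
    for (size_t k = 0; k < hits.size(); ++k) {
        out(k, 0) = hits[k][0]; out(k, 1) = hits[k][1]; out(k, 2) = hits[k][2];
    }
    colnames(out) = CharacterVector::create("start", "end", "dist");
    return out;
}
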