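#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Rows index the query, columns the reference.  Traceback ties are broken
// with fixed precedence diagonal > up > left, where "up" consumes a query
// character (gap in the reference) and "left" consumes a reference character
// (gap in the query).  Counts are therefore reproducible across platforms.

struct NWOut {
    double score;
    int n_mismatches;
    int n_gap_columns;
    std::string aligned_query;
    std::string aligned_reference;
};

static void nw_core(const std::string& q, const std::string& r,
                    double match, double mismatch, double gap,
                    bool build, NWOut& out) {
    const int n = (int)q.size(), m = (int)r.size();
    std::vector<double> H((size_t)(n + 1) * (m + 1));
    const int W = m + 1;
    for (int i = 0; i <= n; ++i) H[(size_t)i * W] = i * gap;
    for (int j = 0; j <= m; ++j) H[j] = j * gap;
    for (int i = 1; i <= n; ++i) {
        const char qc = q[i - 1];
        double* cur = &H[(size_t)i * W];
        const double* prev = &H[(size_t)(i - 1) * W];
        for (int j = 1; j <= m; ++j) {
            double d = prev[j - 1] + (qc == r[j - 1] ? match : mismatch);
            double u = prev[j] + gap;
            double l = cur[j - 1] + gap;
            cur[j] = std::max(d, std::max(u, l));
        }
    }
    out.score = H[(size_t)n * W + m];

    const double eps = 1e-9;
    int i = n, j = m, mm = 0, gc = 0;
    std::string aq, ar;
    if (build) { aq.reserve(n + m); ar.reserve(n + m); }
    while (i > 0 || j > 0) {
        double h = H[(size_t)i * W + j];
        if (i > 0 && j > 0 &&
            std::fabs(h - (H[(size_t)(i - 1) * W + (j - 1)] +
                           (q[i - 1] == r[j - 1] ? match : mismatch))) < eps) {
            if (q[i - 1] != r[j - 1]) ++mm;
            if (build) { aq.push_back(q[i - 1]); ar.push_back(r[j - 1]); }
            --i; --j;
        } else if (i > 0 &&
                   std::fabs(h - (H[(size_t)(i - 1) * W + j] + gap)) < eps) {
            ++gc;
            if (build) { aq.push_back(q[i - 1]); ar.push_back('-'); }
            --i;
        } else {
            ++gc;
            if (build) { aq.push_back('-'); ar.push_back(r[j - 1]); }
            --j;
        }
    }
    if (build) {
        std::reverse(aq.begin(), aq.end());
        std::reverse(ar.begin(), ar.end());
        out.aligned_query = aq;
        out.aligned_reference = ar;
    }
    out.n_mismatches = mm;
    out.n_gap_columns = gc;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string query, std::string reference,
                  double match, double mismatch, double gap) {
    NWOut out;
    nw_core(query, reference, match, mismatch, gap, true, out);
    return List::create(
        _["aligned_query"] = out.aligned_query,
        _["aligned_reference"] = out.aligned_reference,
        _["score"] = out.score,
        _["n_mismatches"] = out.n_mismatches,
        _["n_gap_columns"] = out.n_gap_columns);
}

// [[Rcpp::export]]
NumericMatrix nw_batch_cpp(CharacterVector queries, std::string reference,
                           double match, double mismatch, double gap) {
    const int n = queries.size();
    NumericMatrix res(n, 3);
    colnames(res) = CharacterVector::create("score", "n_mismatches",
                                            "n_gap_columns");
    NWOut out;
    for (int k = 0; k < n; ++k) {
        std::string q = as<std::string>(queries[k]);
        nw_core(q, reference, match, mismatch, gap, false, out);
        res(k, 0) = out.score;
        res(k, 1) = out.n_mismatches;
        res(k, 2) = out.n_gap_columns;
    }
    return res;
}

// Semi-global (free ends on the sequence, full pattern) edit-distance scan:
// the best occurrence of `pat` as an approximate substring of `seq` under
// unit-cost Levenshtein edits.  D[0][j] = 0 (free start), D[i][0] = i.
// Returns, for each end column j, min over starts of the edit distance of
// pat vs seq[start..j].
static void sg_lastrow(const char* pat, int m, const char* seq, int L,
                       std::vector<int>& last) {
    std::vector<int> prev(L + 1), cur(L + 1);
    for (int j = 0; j <= L; ++j) prev[j] = 0;
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        const char pc = pat[i - 1];
        for (int j = 1; j <= L; ++j) {
            int c = prev[j - 1] + (pc == seq[j - 1] ? 0 : 1);
            int u = prev[j] + 1;
            int l = cur[j - 1] + 1;
            cur[j] = std::min(c, std::min(u, l));
        }
        std::swap(prev, cur);
    }
    last = prev;
}

// As above but the start is pinned: D[0][j] = j, so D[m][j] is the edit
// distance of pat vs exactly seq[1..j].
static void fixed_lastrow(const char* pat, int m, const char* seq, int L,
                          std::vector<int>& last) {
    std::vector<int> prev(L + 1), cur(L + 1);
    for (int j = 0; j <= L; ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        const char pc = pat[i - 1];
        for (int j = 1; j <= L; ++j) {
            int c = prev[j - 1] + (pc == seq[j - 1] ? 0 : 1);
            int u = prev[j] + 1;
            int l = cur[j - 1] + 1;
            cur[j] = std::min(c, std::min(u, l));
        }
        std::swap(prev, cur);
    }
    last = prev;
}

// Best occurrence of pat within seq: minimal edit distance, ties broken by
// leftmost start, then shortest span.  1-based inclusive coordinates.
static void anchor_scan_one(const std::string& seq, const std::string& pat,
                            int* start, int* end, int* dist) {
    const int m = (int)pat.size(), L = (int)seq.size();
    std::vector<int> last;
    sg_lastrow(pat.c_str(), m, seq.c_str(), L, last);
    int best = last[0];
    for (int j = 1; j <= L; ++j) best = std::min(best, last[j]);

    // leftmost start achieving `best`: scan the reversed problem, where the
    // last row indexed by jr gives the min distance over occurrences of pat
    // starting at seq position L - jr + 1.
    std::string rp(pat.rbegin(), pat.rend());
    std::string rs(seq.rbegin(), seq.rend());
    std::vector<int> rlast;
    sg_lastrow(rp.c_str(), m, rs.c_str(), L, rlast);
    int s = L + 1;  // empty-suffix start
    for (int jr = L; jr >= 0; --jr) {  // jr = L -> start 1, jr = 0 -> start L+1
        if (rlast[jr] == best) { s = L - jr + 1; break; }
    }

    // shortest end for that start
    int e = s - 1;
    if (s <= L) {
        std::vector<int> row;
        fixed_lastrow(pat.c_str(), m, seq.c_str() + (s - 1), L - s + 1, row);
        for (int j = 0; j <= L - s + 1; ++j) {
            if (row[j] == best) { e = s - 1 + j; break; }
        }
    }
    *start = s;
    *end = e;
    *dist = best;
}

// [[Rcpp::export]]
IntegerVector anchor_scan_cpp(std::string sequence, std::string anchor) {
    int s, e, d;
    anchor_scan_one(sequence, anchor, &s, &e, &d);
    return IntegerVector::create(_["start"] = s, _["end"] = e,
                                 _["distance"] = d);
}

// [[Rcpp::export]]
IntegerMatrix anchor_scan_batch_cpp(CharacterVector sequences,
                                    std::string anchor) {
    const int n = sequences.size();
    IntegerMatrix res(n, 3);
    colnames(res) = CharacterVector::create("start", "end", "distance");
    for (int k = 0; k < n; ++k) {
        std::string s = as<std::string>(sequences[k]);
        int a, b, d;
        anchor_scan_one(s, anchor, &a, &b, &d);
        res(k, 0) = a; res(k, 1) = b; res(k, 2) = d;
    }
    return res;
}
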