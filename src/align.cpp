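#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// Suffix array by prefix doubling over an integer alphabet.
// Text codes must be >= 1; 0 is reserved as the implicit terminator.
static std::vector<int> build_suffix_array(const std::vector<int>& s) {
    int n = (int)s.size();
    std::vector<int> sa(n), rank_(n), tmp(n);
    for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
    for (int k = 1;; k <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
            int ra = a + k < n ? rank_[a + k] : -1;
            int rb = b + k < n ? rank_[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rank_ = tmp;
        if (rank_[sa[n - 1]] == n - 1) break;
    }
    return sa;
}

// Kasai's LCP construction: lcp[i] = LCP(suffix sa[i], suffix sa[i+1]).
static std::vector<int> build_lcp(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
    int n = (int)s.size();
    std::vector<int> rank_(n), lcp(n > 0 ? n - 1 : 0, 0);
    for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank_[i] + 1 < n) {
            int j = sa[rank_[i] + 1];
            while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
            lcp[rank_[i]] = h;
            if (h > 0) --h;
        } else h = 0;
    }
    return lcp;
}

// Maximal unique matches between two coded sequences.
// ref_codes / qry_codes: A,C,G,T as 1..4; every N (or other ambiguity)
// replaced by a unique code >= 5 so it never matches anything, including
// another N.  Returns a 3-column matrix: ref_start, qry_start, length
// (0-based starts).  A MUM occurs exactly once in each sequence and is
// maximal in both directions.
// [[Rcpp::export]]
IntegerMatrix cpp_find_mums(IntegerVector ref_codes, IntegerVector qry_codes,
                            int min_len, int sep_code) {
    int nr = ref_codes.size(), nq = qry_codes.size();
    std::vector<int> s;
    s.reserve(nr + nq + 1);
    for (int i = 0; i < nr; ++i) s.push_back(ref_codes[i]);
    s.push_back(sep_code);  // unique separator, larger than all other codes
    for (int i = 0; i < nq; ++i) s.push_back(qry_codes[i]);
    int n = (int)s.size();
    std::vector<int> sa = build_suffix_array(s);
    std::vector<int> lcp = build_lcp(s, sa);

    std::vector<int> out_r, out_q, out_l;
    for (int i = 0; i + 1 < n; ++i) {
        int a = sa[i], b = sa[i + 1];
        bool a_ref = a < nr, b_ref = b < nr;
        if (a_ref == b_ref) continue;          // need one suffix per sequence
        int L = lcp[i];
        if (L < min_len) continue;
        // unique: no third suffix shares an L-prefix with either member
        if (i > 0 && lcp[i - 1] >= L) continue;
        if (i + 2 < n && lcp[i + 1] >= L) continue;
        // left-maximal: preceding characters differ (sentinels/N are unique)
        if (a > 0 && b > 0 && s[a - 1] == s[b - 1]) continue;
        int rs = a_ref ? a : b;
        int qs = (a_ref ? b : a) - nr - 1;
        out_r.push_back(rs); out_q.push_back(qs); out_l.push_back(L);
    }
    IntegerMatrix m((int)out_r.size(), 3);
    for (int i = 0; i < (int)out_r.size(); ++i) {
        m(i, 0) = out_r[i]; m(i, 1) = out_q[i]; m(i, 2) = out_l[i];
    }
    return m;
}

// Global alignment with affine gaps (Gotoh), full matrix with traceback.
// Used only on short inter-anchor gap segments, so O(nm) is acceptable;
// the caller guards against oversized inputs.  Returns an edit transcript
// over M (match), X (mismatch), I (insertion in query), D (deletion from
// query).  Codes >= 5 (masked N) never match.
// [[Rcpp::export]]
String cpp_affine_global(IntegerVector ref_codes, IntegerVector qry_codes,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
    int n = ref_codes.size(), m = qry_codes.size();
    if (n == 0) return std::string(m, 'I');
    if (m == 0) return std::string(n, 'D');
    const double NEG = -1e18;
    // M-layer: last op diagonal; Ix: gap in ref (insertion); Iy: gap in qry
    std::vector<std::vector<double>> Md(n + 1, std::vector<double>(m + 1, NEG)),
        Ix(n + 1, std::vector<double>(m + 1, NEG)),
        Iy(n + 1, std::vector<double>(m + 1, NEG));
    std::vector<std::vector<char>> Mt(n + 1, std::vector<char>(m + 1, 0)),
        Xt(n + 1, std::vector<char>(m + 1, 0)),
        Yt(n + 1, std::vector<char>(m + 1, 0));
    Md[0][0] = 0;
    for (int j = 1; j <= m; ++j) {
        Ix[0][j] = gap_open + gap_extend * (j - 1);
        Xt[0][j] = j == 1 ? 'M' : 'X';
    }
    for (int i = 1; i <= n; ++i) {
        Iy[i][0] = gap_open + gap_extend * (i - 1);
        Yt[i][0] = i == 1 ? 'M' : 'Y';
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            bool eq = ref_codes[i - 1] == qry_codes[j - 1] &&
                      ref_codes[i - 1] <= 4;
            double sub = eq ? match : mismatch;
            double a = Md[i - 1][j - 1], b = Ix[i - 1][j - 1],
                   c = Iy[i - 1][j - 1];
            double best = a; char t = 'M';
            if (b > best) { best = b; t = 'X'; }
            if (c > best) { best = c; t = 'Y'; }
            if (best > NEG / 2) { Md[i][j] = best + sub; Mt[i][j] = t; }
            // Ix: consume query base j (I op)
            double xo = Md[i][j - 1] + gap_open, xe = Ix[i][j - 1] + gap_extend;
            if (xo >= xe) { Ix[i][j] = xo; Xt[i][j] = 'M'; }
            else { Ix[i][j] = xe; Xt[i][j] = 'X'; }
            // Iy: consume reference base i (D op)
            double yo = Md[i - 1][j] + gap_open, ye = Iy[i - 1][j] + gap_extend;
            if (yo >= ye) { Iy[i][j] = yo; Yt[i][j] = 'M'; }
            else { Iy[i][j] = ye; Yt[i][j] = 'Y'; }
        }
    }
    // traceback
    std::string tr;
    tr.reserve(n + m);
    int i = n, j = m;
    char layer = 'M';
    double best = Md[n][m];
    if (Ix[n][m] > best) { best = Ix[n][m]; layer = 'X'; }
    if (Iy[n][m] > best) { layer = 'Y'; }
    while (i > 0 || j > 0) {
        if (layer == 'M') {
            bool eq = ref_codes[i - 1] == qry_codes[j - 1] &&
                      ref_codes[i - 1] <= 4;
            tr.push_back(eq ? 'M' : 'X');
            layer = Mt[i][j];
            --i; --j;
        } else if (layer == 'X') {
            tr.push_back('I');
            char prev = Xt[i][j];
            --j;
            layer = prev == 'M' ? 'M' : 'X';
            if (j == 0 && i == 0) break;
            if (j == 0 && layer == 'X') layer = 'Y';  // defensive; unreachable
        } else {
            tr.push_back('D');
            char prev = Yt[i][j];
            --i;
            layer = prev == 'M' ? 'M' : 'Y';
        }
    }
    std::reverse(tr.begin(), tr.end());
    return tr;
}
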