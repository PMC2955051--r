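#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); robust to the highly
// repetitive texts typical of TE families, where plain suffix sorting
// degenerates.
static void suffix_array(const std::vector<int>& t, std::vector<int>& sa) {
    const int n = (int) t.size();
    sa.resize(n);
    std::vector<int> rnk(n), tmp(n);
    for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = t[i]; }
    for (int k = 1;; k <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            int ra = a + k < n ? rnk[a + k] : -1;
            int rb = b + k < n ? rnk[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
    }
}

// Kasai LCP: lcp[i] = LCP(sa[i-1], sa[i]) for i in 1..n-1.
static void lcp_array(const std::vector<int>& t, const std::vector<int>& sa,
                      std::vector<int>& lcp) {
    const int n = (int) t.size();
    std::vector<int> rnk(n);
    for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
    lcp.assign(n, 0);
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rnk[i] > 0) {
            int j = sa[rnk[i] - 1];
            while (i + h < n && j + h < n && t[i + h] == t[j + h]) ++h;
            lcp[rnk[i]] = h;
            if (h > 0) --h;
        } else h = 0;
    }
}

// Enumerate maximal repeats of an integer text. Letters: A,C,G,T mapped to
// 1..4 by the caller; every sentinel (sequence separator, N) carries a
// unique code > 4 so no repeated word can span one. A word is a maximal
// repeat iff it is the label of an internal suffix-tree node (an
// LCP-interval: right-maximal by construction) whose occurrence set is
// left-diverse (>= 2 distinct preceding letters; the virtual letter before
// position 0 is unique).
//
// Returns list(len = integer vector, occ = list of integer vectors of
// 0-based start positions in the text).
// [[Rcpp::export]]
List mr_enumerate_cpp(IntegerVector text) {
    const int n = text.size();
    std::vector<int> t(text.begin(), text.end());
    if (n == 0) return List::create(_["len"] = IntegerVector(0), _["occ"] = List(0));
    std::vector<int> sa, lcp;
    suffix_array(t, sa);
    lcp_array(t, sa, lcp);

    // preceding letter of each text position; -1 is a unique virtual letter
    // before the first position (positions after a sentinel inherit that
    // sentinel's unique code).
    std::vector<int> prevc(n);
    prevc[0] = -1;
    for (int i = 1; i < n; ++i) prevc[i] = t[i - 1];

    std::vector<int> out_len;
    std::vector< std::vector<int> > out_occ;

    // stack-based LCP-interval enumeration
    std::vector< std::pair<int,int> > stk; // (lcp value, left boundary)
    stk.push_back(std::make_pair(0, 0));
    for (int i = 1; i <= n; ++i) {
        int l = (i < n) ? lcp[i] : 0;
        int lb = i - 1;
        while (l < stk.back().first) {
            int ilcp = stk.back().first;
            int ilb  = stk.back().second;
            stk.pop_back();
            int irb = i - 1; // interval [ilb, irb] over SA indices
            lb = ilb;
            if (ilcp > 0) {
                // left-diversity check
                int first = prevc[sa[ilb]];
                bool diverse = false;
                for (int k = ilb + 1; k <= irb; ++k)
                    if (prevc[sa[k]] != first) { diverse = true; break; }
                if (diverse) {
                    std::vector<int> occ(sa.begin() + ilb, sa.begin() + irb + 1);
                    std::sort(occ.begin(), occ.end());
                    out_len.push_back(ilcp);
                    out_occ.push_back(occ);
                }
            }
        }
        if (i < n && l > stk.back().first)
            stk.push_back(std::make_pair(l, lb));
    }

    const int m = (int) out_len.size();
    List occs(m);
    IntegerVector lens(m);
    for (int j = 0; j < m; ++j) {
        lens[j] = out_len[j];
        occs[j] = IntegerVector(out_occ[j].begin(), out_occ[j].end());
    }
    return List::create(_["len"] = lens, _["occ"] = occs);
}
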