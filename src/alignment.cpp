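#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming kernels shared by the sequence and
// profile aligners. A gap run of length L is penalized gap_open +
// L * gap_extend (Biostrings convention, penalties given positive).
//
// States: M = positions i of the first input and j of the second aligned,
// GA = gap in the first input (consumes j), GB = gap in the second
// (consumes i). Ties are resolved M > GA > GB, giving the documented
// deterministic preference for match/mismatch over gap-in-a over gap-in-b.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(NumericMatrix S, double gap_open, double gap_extend) {
    const int n = S.nrow(), m = S.ncol();
    // DP tables, (n+1) x (m+1)
    NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
    IntegerMatrix tbM(n + 1, m + 1), tbGA(n + 1, m + 1), tbGB(n + 1, m + 1);
    // traceback codes: 1 = came from M, 2 = from GA, 3 = from GB
    M(0, 0) = 0.0; GA(0, 0) = NEG_INF; GB(0, 0) = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        M(0, j) = NEG_INF; GB(0, j) = NEG_INF;
        GA(0, j) = -(gap_open + j * gap_extend);
        tbGA(0, j) = 2;
    }
    for (int i = 1; i <= n; ++i) {
        M(i, 0) = NEG_INF; GA(i, 0) = NEG_INF;
        GB(i, 0) = -(gap_open + i * gap_extend);
        tbGB(i, 0) = 3;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            // M
            double a = M(i - 1, j - 1), b = GA(i - 1, j - 1), c = GB(i - 1, j - 1);
            int t = 1; double best = a;
            if (b > best) { best = b; t = 2; }
            if (c > best) { best = c; t = 3; }
            M(i, j) = best + S(i - 1, j - 1);
            tbM(i, j) = t;
            // GA: gap in first input, consume j
            a = M(i, j - 1) - (gap_open + gap_extend);
            b = GA(i, j - 1) - gap_extend;
            c = GB(i, j - 1) - (gap_open + gap_extend);
            t = 1; best = a;
            if (b > best) { best = b; t = 2; }
            if (c > best) { best = c; t = 3; }
            GA(i, j) = best; tbGA(i, j) = t;
            // GB: gap in second input, consume i
            a = M(i - 1, j) - (gap_open + gap_extend);
            b = GA(i - 1, j) - (gap_open + gap_extend);
            c = GB(i - 1, j) - gap_extend;
            t = 1; best = a;
            if (b > best) { best = b; t = 2; }
            if (c > best) { best = c; t = 3; }
            GB(i, j) = best; tbGB(i, j) = t;
        }
    }
    double score = M(n, m); int state = 1;
    if (GA(n, m) > score) { score = GA(n, m); state = 2; }
    if (GB(n, m) > score) { score = GB(n, m); state = 3; }

    std::vector<int> pa, pb;  // consumed 1-based indices, 0 = gap
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 1) {
            int prev = tbM(i, j);
            pa.push_back(i); pb.push_back(j);
            --i; --j; state = prev;
        } else if (state == 2) {
            int prev = tbGA(i, j);
            pa.push_back(0); pb.push_back(j);
            --j; state = prev;
        } else {
            int prev = tbGB(i, j);
            pa.push_back(i); pb.push_back(0);
            --i; state = prev;
        }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());
    return List::create(_["score"] = score,
                        _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                        _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Smith-Waterman local score (score only) for zero-based integer-encoded
// sequences against a flat substitution matrix. Used by similarity_search.
static double sw_score_one(const std::vector<int> &a, const std::vector<int> &b,
                           const double *S, int nalpha,
                           double gap_open, double gap_extend,
                           std::vector<double> &H, std::vector<double> &E) {
    const int n = (int)a.size(), m = (int)b.size();
    const double go = gap_open + gap_extend, ge = gap_extend;
    // H[j]: best score ending at (i, j) in any state (local, floored at 0)
    // E[j]: best score ending with a vertical gap run (gap in b)
    H.assign(m + 1, 0.0);
    E.assign(m + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
        const double *subrow = S + (size_t)a[i - 1] * nalpha;
        double diag = 0.0;       // H[i-1][j-1]
        double F = NEG_INF;      // horizontal gap run (gap in a)
        for (int j = 1; j <= m; ++j) {
            E[j] = std::max(H[j] - go, E[j] - ge);
            F = std::max(H[j - 1] - go, F - ge);
            double h = diag + subrow[b[j - 1]];
            if (E[j] > h) h = E[j];
            if (F > h) h = F;
            if (h < 0.0) h = 0.0;
            diag = H[j];
            H[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".sw_score_pairs_cpp")]]
NumericVector sw_score_pairs_cpp(List seqs_a, List seqs_b, NumericMatrix sub,
                                 double gap_open, double gap_extend,
                                 IntegerMatrix pairs) {
    const int nalpha = sub.nrow();
    std::vector<double> S((size_t)nalpha * nalpha);
    for (int r = 0; r < nalpha; ++r)
        for (int c = 0; c < nalpha; ++c)
            S[(size_t)r * nalpha + c] = sub(r, c);
    auto conv = [](List L) {
        std::vector<std::vector<int>> v(L.size());
        for (R_xlen_t i = 0; i < L.size(); ++i) {
            IntegerVector x = L[i];
            v[i].resize(x.size());
            for (R_xlen_t j = 0; j < x.size(); ++j) v[i][j] = x[j] - 1;
        }
        return v;
    };
    std::vector<std::vector<int>> A = conv(seqs_a), B = conv(seqs_b);
    const int np = pairs.nrow();
    NumericVector out(np);
    std::vector<double> H, E;
    for (int k = 0; k < np; ++k) {
        out[k] = sw_score_one(A[pairs(k, 0) - 1], B[pairs(k, 1) - 1],
                              S.data(), nalpha, gap_open, gap_extend, H, E);
        if (k % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}
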