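#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman, BLASTN-style costs: a gap of length k costs
// gap_open + k * gap_extend. Returns score and 1-based aligned ranges in
// query and subject for the best-scoring local alignment.
static void sw_one(const std::string &q, const std::string &s,
                   int match, int mismatch, int gap_open, int gap_extend,
                   int out[5]) {
    const int n = (int)q.size(), m = (int)s.size();
    const int NEG = -1000000;
    // H: best ending in (i,j) with match/mismatch; E: gap in query (consumes
    // subject); F: gap in subject (consumes query).
    std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
    std::vector<std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
    std::vector<std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            E[i][j] = std::max(E[i][j - 1] - gap_extend,
                               H[i][j - 1] - gap_open - gap_extend);
            F[i][j] = std::max(F[i - 1][j] - gap_extend,
                               H[i - 1][j] - gap_open - gap_extend);
            int sc = (q[i - 1] == s[j - 1]) ? match : mismatch;
            int h = H[i - 1][j - 1] + sc;
            if (E[i][j] > h) h = E[i][j];
            if (F[i][j] > h) h = F[i][j];
            if (h < 0) h = 0;
            H[i][j] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    // traceback from (bi, bj) until a zero cell
    int i = bi, j = bj;
    int qs = bi, qe = bi, ss = bj, se = bj;
    if (best > 0) {
        int state = 0; // 0 = H, 1 = E, 2 = F
        while (i > 0 && j > 0) {
            if (state == 0) {
                if (H[i][j] == 0) break;
                int sc = (q[i - 1] == s[j - 1]) ? match : mismatch;
                if (H[i][j] == H[i - 1][j - 1] + sc) { --i; --j; }
                else if (H[i][j] == E[i][j]) state = 1;
                else state = 2;
            } else if (state == 1) {
                if (E[i][j] == H[i][j - 1] - gap_open - gap_extend) {
                    --j; state = 0;
                } else { --j; }
            } else {
                if (F[i][j] == H[i - 1][j] - gap_open - gap_extend) {
                    --i; state = 0;
                } else { --i; }
            }
        }
        qs = i + 1; ss = j + 1;
    } else {
        qs = qe = ss = se = 0;
    }
    out[0] = best; out[1] = qs; out[2] = qe; out[3] = ss; out[4] = se;
}

// [[Rcpp::export]]
IntegerVector sw_align_cpp(std::string query, std::string subject,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
    int out[5];
    sw_one(query, subject, match, mismatch, gap_open, gap_extend, out);
    IntegerVector res(5);
    for (int k = 0; k < 5; ++k) res[k] = out[k];
    res.names() = CharacterVector::create("score", "qstart", "qend",
                                          "sstart", "send");
    return res;
}

// [[Rcpp::export]]
IntegerMatrix sw_align_batch_cpp(CharacterVector query,
                                 CharacterVector subject,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
    int nr = query.size();
    IntegerMatrix res(nr, 5);
    int out[5];
    for (int r = 0; r < nr; ++r) {
        std::string q = as<std::string>(query[r]);
        std::string s = as<std::string>(subject[r]);
        sw_one(q, s, match, mismatch, gap_open, gap_extend, out);
        for (int k = 0; k < 5; ++k) res(r, k) = out[k];
    }
    colnames(res) = CharacterVector::create("score", "qstart", "qend",
                                            "sstart", "send");
    return res;
}
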