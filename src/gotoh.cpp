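#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Gotoh global alignment with affine gaps.  A gap run of length L scores
// gap_open + L * gap_extend (both penalties are <= 0).  Three-state DP:
//   M: column is a match/mismatch
//   X: column consumes a character of `a` against a gap in `b` ("up")
//   Y: column consumes a character of `b` against a gap in `a` ("left")
// Ties are broken M > X > Y everywhere (DP predecessor choice and final
// state), which fixes the traceback deterministically: diagonal > up > left.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum State : unsigned char { SM = 0, SX = 1, SY = 2, SNONE = 3 };

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
    const int n = (int) a.size();
    const int m = (int) b.size();

    // rolling score rows; full pointer matrices (one byte per state per cell)
    std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
    std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
    std::vector<unsigned char> ptrM((size_t)(n + 1) * (m + 1), SNONE);
    std::vector<unsigned char> ptrX((size_t)(n + 1) * (m + 1), SNONE);
    std::vector<unsigned char> ptrY((size_t)(n + 1) * (m + 1), SNONE);
    const size_t W = (size_t) m + 1;

    Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mprev[j] = NEG_INF;
        Xprev[j] = NEG_INF;
        Yprev[j] = gap_open + j * gap_extend;
        ptrY[(size_t)0 * W + j] = (j == 1) ? SM : SY;
    }

    for (int i = 1; i <= n; ++i) {
        Mcur[0] = NEG_INF;
        Xcur[0] = gap_open + i * gap_extend;
        Ycur[0] = NEG_INF;
        ptrX[(size_t)i * W + 0] = (i == 1) ? SM : SX;

        const char ai = a[(size_t) i - 1];
        for (int j = 1; j <= m; ++j) {
            const char bj = b[(size_t) j - 1];
            // N never matches (ambiguous base)
            const double s = (ai == bj && ai != 'N') ? match : mismatch;

            // M from diagonal predecessors, preference M > X > Y
            double best = Mprev[j - 1]; unsigned char st = SM;
            if (Xprev[j - 1] > best) { best = Xprev[j - 1]; st = SX; }
            if (Yprev[j - 1] > best) { best = Yprev[j - 1]; st = SY; }
            Mcur[j] = (best == NEG_INF) ? NEG_INF : best + s;
            ptrM[(size_t)i * W + j] = st;

            // X: gap in b, move up (consume a_i)
            double xo = (Mprev[j] == NEG_INF) ? NEG_INF : Mprev[j] + gap_open + gap_extend;
            double xe = (Xprev[j] == NEG_INF) ? NEG_INF : Xprev[j] + gap_extend;
            double xy = (Yprev[j] == NEG_INF) ? NEG_INF : Yprev[j] + gap_open + gap_extend;
            best = xo; st = SM;
            if (xe > best) { best = xe; st = SX; }
            if (xy > best) { best = xy; st = SY; }
            Xcur[j] = best;
            ptrX[(size_t)i * W + j] = st;

            // Y: gap in a, move left (consume b_j)
            double yo = (Mcur[j - 1] == NEG_INF) ? NEG_INF : Mcur[j - 1] + gap_open + gap_extend;
            double yx = (Xcur[j - 1] == NEG_INF) ? NEG_INF : Xcur[j - 1] + gap_open + gap_extend;
            double ye = (Ycur[j - 1] == NEG_INF) ? NEG_INF : Ycur[j - 1] + gap_extend;
            best = yo; st = SM;
            if (yx > best) { best = yx; st = SX; }
            if (ye > best) { best = ye; st = SY; }
            Ycur[j] = best;
            ptrY[(size_t)i * W + j] = st;
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }

    double score = Mprev[m]; unsigned char state = SM;
    if (Xprev[m] > score) { score = Xprev[m]; state = SX; }
    if (Yprev[m] > score) { score = Yprev[m]; state = SY; }
    if (n == 0 && m == 0) { score = 0.0; state = SM; }

    // traceback
    std::string ga, gb;
    ga.reserve(n + m); gb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == SM && i > 0 && j > 0) {
            ga.push_back(a[(size_t) i - 1]);
            gb.push_back(b[(size_t) j - 1]);
            state = ptrM[(size_t)i * W + j];
            --i; --j;
        } else if (state == SX || (state == SM && j == 0)) {
            ga.push_back(a[(size_t) i - 1]);
            gb.push_back('-');
            state = ptrX[(size_t)i * W + j];
            --i;
        } else { // SY, or SM with i == 0
            ga.push_back('-');
            gb.push_back(b[(size_t) j - 1]);
            state = ptrY[(size_t)i * W + j];
            --j;
        }
    }
    std::reverse(ga.begin(), ga.end());
    std::reverse(gb.begin(), gb.end());

    return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                        _["score"] = score);
}
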