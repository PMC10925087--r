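// Banded, base-quality-aware pair-HMM forward pass for read-haplotype
// likelihoods, plus a small pileup accumulator.
//
// Model: states M/I/D with transitions
//   M->I = M->D = gapOpen, M->M = 1 - 2*gapOpen,
//   I->I = D->D = gapExtend, I->M = D->M = 1 - gapExtend.
// The haplotype flanks are free: row 0 carries 1/L of deletion-state mass at
// every column (uniform start position) and the likelihood sums the match
// states of the final read row over all columns (free right flank). Paths
// start and end in a match state, which keeps the model exactly symmetric
// under joint reversal of read and haplotype.
// Match emissions come from the capped base quality q:
//   matching base 1 - 10^(-q/10), each other base 10^(-q/10)/3,
// with 1/4 for any comparison involving N. Insertions emit 1/4.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double emitMatch(char rb, char hb, double pe) {
    if (rb == 'N' || hb == 'N' || rb == 'n' || hb == 'n') return 0.25;
    return (rb == hb) ? 1.0 - pe : pe / 3.0;
}

static double phmmForwardOne(const char *read, const int *qual, int n,
                             const char *hap, int L, double gapOpen,
                             double gapExtend, int band, int maxQual) {
    const double tMM = 1.0 - 2.0 * gapOpen, tMI = gapOpen, tMD = gapOpen;
    const double tII = gapExtend, tIM = 1.0 - gapExtend;
    const double tDD = gapExtend, tDM = 1.0 - gapExtend;
    const double eIns = 0.25;

    if (n < 1 || L < 1) return R_NegInf;
    if (L - n + 2 * band < 0) return NA_REAL;  // band cannot connect endpoints

    std::vector<double> Mp(L + 1, 0.0), Ip(L + 1, 0.0), Dp(L + 1, 0.0);
    std::vector<double> Mc(L + 1, 0.0), Ic(L + 1, 0.0), Dc(L + 1, 0.0);
    for (int j = 0; j <= L; ++j) Dp[j] = 1.0 / L;

    double logScale = 0.0;
    for (int i = 1; i <= n; ++i) {
        int lo = i - band, hi = i + (L - n) + band;
        if (lo < 1) lo = 1;
        if (hi > L) hi = L;
        std::fill(Mc.begin(), Mc.end(), 0.0);
        std::fill(Ic.begin(), Ic.end(), 0.0);
        std::fill(Dc.begin(), Dc.end(), 0.0);
        int q = qual[i - 1];
        if (q > maxQual) q = maxQual;
        if (q < 0) q = 0;
        double pe = std::pow(10.0, -q / 10.0);
        for (int j = lo; j <= hi; ++j) {
            double em = emitMatch(read[i - 1], hap[j - 1], pe);
            Mc[j] = em * (tMM * Mp[j - 1] + tIM * Ip[j - 1] + tDM * Dp[j - 1]);
            Ic[j] = eIns * (tMI * Mp[j] + tII * Ip[j]);
            Dc[j] = tMD * Mc[j - 1] + tDD * Dc[j - 1];
        }
        double s = 0.0;
        for (int j = 0; j <= L; ++j) s += Mc[j] + Ic[j] + Dc[j];
        if (s <= 0.0) return R_NegInf;  // no path mass inside the band
        double inv = 1.0 / s;
        for (int j = 0; j <= L; ++j) { Mc[j] *= inv; Ic[j] *= inv; Dc[j] *= inv; }
        logScale += std::log(s);
        Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
    }
    double tot = 0.0;
    for (int j = 1; j <= L; ++j) tot += Mp[j];
    if (tot <= 0.0) return R_NegInf;
    return logScale + std::log(tot);
}

// quals are PHRED+33 encoded strings, one character per read base
// [[Rcpp::export(name = ".phmmForwardBatch")]]
NumericVector phmmForwardBatch(CharacterVector reads, CharacterVector quals,
                               CharacterVector haps, double gapOpen,
                               double gapExtend, int band, int maxQual) {
    int m = reads.size();
    if (quals.size() != m || haps.size() != m)
        stop("reads, quals and haps must have equal length");
    NumericVector out(m);
    std::vector<int> q;
    for (int k = 0; k < m; ++k) {
        String rs(reads[k]), qs(quals[k]), hs(haps[k]);
        const char *r = rs.get_cstring();
        const char *qc = qs.get_cstring();
        const char *h = hs.get_cstring();
        int n = std::strlen(r), L = std::strlen(h);
        if ((int)std::strlen(qc) != n)
            stop("quality string length mismatch at record %d", k + 1);
        q.resize(n);
        for (int i = 0; i < n; ++i) q[i] = qc[i] - 33;
        out[k] = phmmForwardOne(r, q.data(), n, h, L, gapOpen, gapExtend,
                                band, maxQual);
    }
    return out;
}

// Accumulate base counts per reference position from reference-projected
// read sequences ('-' marks deletions, which are not counted).
// Returns a 4 x L matrix with rows A, C, G, T; region is
// [regionStart, regionStart + L) in the same coordinates as starts (1-based).
// [[Rcpp::export(name = ".pileupCounts")]]
IntegerMatrix pileupCounts(IntegerVector starts, CharacterVector seqs,
                           int regionStart, int L) {
    IntegerMatrix counts(4, L);
    int m = seqs.size();
    if (starts.size() != m) stop("starts and seqs must have equal length");
    for (int k = 0; k < m; ++k) {
        String ss(seqs[k]);
        const char *s = ss.get_cstring();
        int len = std::strlen(s);
        int off = starts[k] - regionStart;
        for (int i = 0; i < len; ++i) {
            int col = off + i;
            if (col < 0 || col >= L) continue;
            int row;
            switch (s[i]) {
            case 'A': case 'a': row = 0; break;
            case 'C': case 'c': row = 1; break;
            case 'G': case 'g': row = 2; break;
            case 'T': case 't': row = 3; break;
            default: continue;
            }
            counts(row, col) += 1;
        }
    }
    return counts;
}
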