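#include "xenosort_types.h"
using namespace Rcpp;

typedef XPtr<CuckooStore> StorePtr;

// category columns: h, hw, g, gw, b, x, n
static void tally_read(const CuckooStore *st, const char *s, int *acc) {
    int k = st->k;
    uint64_t mask = st->mask;
    int shift = 2 * (k - 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (const char *c = s; *c; ++c) {
        int b = base_code(*c);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) {
            int v = st->lookup(fwd > rc ? fwd : rc);
            switch (v) {
            case 1: ++acc[0]; break;
            case 5: ++acc[1]; break;
            case 2: ++acc[2]; break;
            case 6: ++acc[3]; break;
            case 3: ++acc[4]; break;
            default: ++acc[5]; break; // absent
            }
            ++acc[6];
        }
    }
}

// Per-fragment k-mer category counts (h, hw, g, gw, b, x, n); mates summed.
// [[Rcpp::export(name = ".cpp_fragment_stats")]]
IntegerMatrix cpp_fragment_stats(SEXP sp, CharacterVector reads1,
                                 Nullable<CharacterVector> reads2) {
    StorePtr st(sp);
    R_xlen_t n = reads1.size();
    CharacterVector r2;
    bool paired = reads2.isNotNull();
    if (paired) {
        r2 = reads2.get();
        if (r2.size() != n) stop("paired read vectors must have equal length");
    }
    IntegerMatrix out(n, 7);
    colnames(out) = CharacterVector::create("h", "hw", "g", "gw", "b", "x", "n");
    for (R_xlen_t i = 0; i < n; ++i) {
        int acc[7] = {0, 0, 0, 0, 0, 0, 0};
        tally_read(st, CHAR(reads1[i]), acc);
        if (paired) tally_read(st, CHAR(r2[i]), acc);
        for (int c = 0; c < 7; ++c) out(i, c) = acc[c];
    }
    return out;
}

// Quick-mode sampling: category of the 3rd and 3rd-last valid k-mer of a
// read.  Categories: 0 host (incl. weak host), 1 graft (incl. weak graft),
// 2 both, 3 absent; -1 = read has fewer than 3 valid k-mers.
static void sample_read(const CuckooStore *st, const char *s, int cat[2]) {
    int k = st->k;
    uint64_t mask = st->mask;
    int shift = 2 * (k - 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    std::vector<uint64_t> valid;
    for (const char *c = s; *c; ++c) {
        int b = base_code(*c);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) valid.push_back(fwd > rc ? fwd : rc);
    }
    if (valid.size() < 3) { cat[0] = cat[1] = -1; return; }
    uint64_t picks[2] = {valid[2], valid[valid.size() - 3]};
    for (int i = 0; i < 2; ++i) {
        int v = st->lookup(picks[i]);
        if (v == 1 || v == 5) cat[i] = 0;
        else if (v == 2 || v == 6) cat[i] = 1;
        else if (v == 3) cat[i] = 2;
        else cat[i] = 3;
    }
}

// Returns, per fragment, the agreed sampled category (0 host, 1 graft,
// 2 both, 3 absent/neither) or -1 when the samples disagree or a read is
// too short, in which case the caller falls back to full counting.
// [[Rcpp::export(name = ".cpp_quick_sample")]]
IntegerVector cpp_quick_sample(SEXP sp, CharacterVector reads1,
                               Nullable<CharacterVector> reads2) {
    StorePtr st(sp);
    R_xlen_t n = reads1.size();
    CharacterVector r2;
    bool paired = reads2.isNotNull();
    if (paired) {
        r2 = reads2.get();
        if (r2.size() != n) stop("paired read vectors must have equal length");
    }
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        int c1[2], c2[2] = {0, 0};
        sample_read(st, CHAR(reads1[i]), c1);
        if (paired) sample_read(st, CHAR(r2[i]), c2);
        bool ok = c1[0] >= 0 && c1[0] == c1[1];
        if (paired) ok = ok && c2[0] >= 0 && c2[0] == c2[1] && c2[0] == c1[0];
        out[i] = ok ? c1[0] : -1;
    }
    return out;
}
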