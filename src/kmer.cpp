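#include "xenosort_types.h"
using namespace Rcpp;

// Encoding primitives. Keys cross the R boundary as doubles, which represent
// integers exactly up to 2^53; R-level wrappers restrict per-key interfaces
// to k <= 26 (2k <= 52 bits) for that reason.

// [[Rcpp::export(name = ".cpp_encode_kmer")]]
NumericVector cpp_encode_kmer(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_REAL; continue; }
        const char *s = CHAR(seqs[i]);
        uint64_t code = 0;
        bool ok = true;
        int len = 0;
        for (const char *c = s; *c; ++c, ++len) {
            int b = base_code(*c);
            if (b < 0) { ok = false; }
            code = (code << 2) | (uint64_t)(b < 0 ? 0 : b);
        }
        if (len < 1 || len > 26) stop("k-mer length must be in 1..26");
        out[i] = ok ? (double)code : NA_REAL;  // NA is the invalid-k-mer sentinel
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_decode_kmer")]]
CharacterVector cpp_decode_kmer(NumericVector codes, int k) {
    R_xlen_t n = codes.size();
    CharacterVector out(n);
    std::string buf(k, 'A');
    for (R_xlen_t i = 0; i < n; ++i) {
        if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
        uint64_t x = (uint64_t)codes[i];
        for (int j = k - 1; j >= 0; --j) { buf[j] = code_base((int)(x & 3)); x >>= 2; }
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_revcomp_code")]]
NumericVector cpp_revcomp_code(NumericVector codes, int k) {
    R_xlen_t n = codes.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (NumericVector::is_na(codes[i])) { out[i] = NA_REAL; continue; }
        out[i] = (double)revcomp_code64((uint64_t)codes[i], k);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_canonical_code")]]
NumericVector cpp_canonical_code(NumericVector codes, int k) {
    R_xlen_t n = codes.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (NumericVector::is_na(codes[i])) { out[i] = NA_REAL; continue; }
        out[i] = (double)canonical_code64((uint64_t)codes[i], k);
    }
    return out;
}

// Valid windows of length k (A/C/G/T/U only); 0-based positions.
// [[Rcpp::export(name = ".cpp_canonical_kmers")]]
List cpp_canonical_kmers(std::string seq, int k) {
    std::vector<double> pos, code;
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    int shift = 2 * (k - 1);
    for (size_t i = 0; i < seq.size(); ++i) {
        int b = base_code(seq[i]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) {
            pos.push_back((double)(i + 1 - k));
            code.push_back((double)(fwd > rc ? fwd : rc));
        }
    }
    return List::create(_["pos"] = wrap(pos), _["code"] = wrap(code));
}

// ---- affine bijective hashing (module-level, store-independent) ----------

// [[Rcpp::export(name = ".cpp_rot_half")]]
NumericVector cpp_rot_half(NumericVector x, int k) {
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    R_xlen_t n = x.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t v = (uint64_t)x[i];
        out[i] = (double)(((v << k) | (v >> k)) & mask);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_g_forward")]]
NumericVector cpp_g_forward(NumericVector x, double a, double b, int k) {
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t ua = (uint64_t)a, ub = (uint64_t)b;
    R_xlen_t n = x.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t v = (uint64_t)x[i];
        uint64_t r = ((v << k) | (v >> k)) & mask;
        out[i] = (double)((ua * (r ^ ub)) & mask);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_g_inverse")]]
NumericVector cpp_g_inverse(NumericVector y, double a, double b, int k) {
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t ainv = odd_inverse((uint64_t)a, mask), ub = (uint64_t)b;
    R_xlen_t n = y.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        uint64_t v = ((ainv * (uint64_t)y[i]) & mask) ^ ub;
        out[i] = (double)(((v << k) | (v >> k)) & mask);
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_quotient_bits")]]
int cpp_quotient_bits(int k, double p) {
    return CuckooStore::quotient_width(k, (uint64_t)p);
}
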