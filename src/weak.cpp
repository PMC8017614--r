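#include "xenosort_types.h"
using namespace Rcpp;

typedef XPtr<CuckooStore> StorePtr;

// Insert every valid canonical k-mer of each sequence with the given species
// value (1 host, 2 graft).  Returns FALSE on construction failure.
// [[Rcpp::export(name = ".cpp_store_insert_sequences")]]
bool cpp_store_insert_sequences(SEXP sp, CharacterVector seqs, int value) {
    StorePtr st(sp);
    int k = st->k;
    uint64_t mask = st->mask;
    int shift = 2 * (k - 1);
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char *str = CHAR(seqs[s]);
        uint64_t fwd = 0, rc = 0;
        int run = 0;
        for (const char *c = str; *c; ++c) {
            int b = base_code(*c);
            if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
            if (++run >= k) {
                if (st->insert(fwd > rc ? fwd : rc, value) == -1) return false;
            }
        }
    }
    return true;
}

// ---- weak k-mer annotation ------------------------------------------------
// A host-exclusive k-mer is weak if some Hamming-distance-1 neighbor carries
// the graft bit (value 2 or 3), and symmetrically for graft.  At annotation
// time stored values are in {1,2,3}.

static inline bool cross_species(int v1, int v2) {
    // v1 is the candidate, v2 the neighbor; weak bits (value 4) are ignored
    // so re-annotation is a no-op
    v1 &= 3; v2 &= 3;
    if (v1 == 1) return v2 == 2 || v2 == 3;
    if (v1 == 2) return v2 == 1 || v2 == 3;
    return false;
}

// bit-parallel test: do two 2-bit-encoded words differ in exactly one base?
static inline bool differs_one_base(uint64_t d) {
    if (d == 0) return false;
    int t = __builtin_ctzll(d) & ~1;   // align to the 2-bit base boundary
    return (d & ~(3ULL << t)) == 0;
}

struct LEntry {
    uint64_t code;     // one orientation of the k-mer
    uint8_t value;     // species value of the canonical k-mer
};

// Chunked extract-sort-scan annotation.  chunks must be 4^c with c in {0,1,2}
// and c <= l where k = 2l + 1 (the chunk prefix must not touch the middle base).
// [[Rcpp::export(name = ".cpp_mark_weak_chunked")]]
double cpp_mark_weak_chunked(SEXP sp, int chunks) {
    StorePtr st(sp);
    int k = st->k;
    if (k % 2 == 0) stop("weak-k-mer annotation requires odd k");
    int l = (k - 1) / 2;
    int cbases;
    if (chunks == 1) cbases = 0;
    else if (chunks == 4) cbases = 1;
    else if (chunks == 16) cbases = 2;
    else stop("chunks must be 1, 4 or 16");
    if (cbases > l) stop("too many chunks for this k (chunk prefix reaches the middle base)");

    uint64_t smask = (l > 0) ? ((1ULL << (2 * l)) - 1ULL) : 0ULL; // l-suffix mask
    uint64_t outer_mask = st->mask & ~(3ULL << (2 * l));          // all but middle base
    std::vector<uint64_t> marks;

    for (int chunk = 0; chunk < chunks; ++chunk) {
        // (1) extract this chunk of the full list L (both orientations)
        std::vector<LEntry> L;
        for (uint64_t f = 0; f < st->p; ++f) {
            for (int j = 0; j < CuckooStore::B; ++j) {
                int c = st->slot_choice(f, j);
                if (c == 0) break;
                uint64_t key = st->reconstruct(c - 1, f, st->slot_quot(f, j));
                uint8_t v = (uint8_t)st->slot_value(f, j);
                uint64_t orient[2] = {key, revcomp_code64(key, k)};
                for (int o = 0; o < 2; ++o) {
                    if (cbases == 0 ||
                        (int)(orient[o] >> (2 * (k - cbases))) == chunk)
                        L.push_back(LEntry{orient[o], v});
                }
            }
        }
        // (2) sort; scan blocks of constant (l+1)-prefix; all suffix pairs
        std::sort(L.begin(), L.end(),
                  [](const LEntry &a, const LEntry &b) { return a.code < b.code; });
        size_t i = 0;
        while (i < L.size()) {
            size_t j = i + 1;
            while (j < L.size() && (L[j].code >> (2 * l)) == (L[i].code >> (2 * l))) ++j;
            for (size_t a = i; a < j; ++a) {
                for (size_t b = a + 1; b < j; ++b) {
                    uint64_t d = (L[a].code ^ L[b].code) & smask;
                    if (differs_one_base(d)) {
                        if (cross_species(L[a].value, L[b].value))
                            marks.push_back(canonical_code64(L[a].code, k));
                        if (cross_species(L[b].value, L[a].value))
                            marks.push_back(canonical_code64(L[b].code, k));
                    }
                }
            }
            i = j;
        }
        // (3) re-partition by constant l-prefix; re-sort with middle base and
        // l-suffix swapped; pairs agreeing on the 2l outer bases differ only
        // in the middle base
        i = 0;
        while (i < L.size()) {
            size_t j = i + 1;
            while (j < L.size() &&
                   (L[j].code >> (2 * (l + 1))) == (L[i].code >> (2 * (l + 1)))) ++j;
            std::sort(L.begin() + i, L.begin() + j,
                      [l, smask](const LEntry &a, const LEntry &b) {
                          uint64_t ka = ((a.code & smask) << 2) | ((a.code >> (2 * l)) & 3ULL);
                          uint64_t kb = ((b.code & smask) << 2) | ((b.code >> (2 * l)) & 3ULL);
                          return ka < kb;
                      });
            size_t a = i;
            while (a < j) {
                size_t b = a + 1;
                while (b < j && ((L[b].code ^ L[a].code) & outer_mask) == 0) ++b;
                for (size_t u = a; u < b; ++u)
                    for (size_t v = u + 1; v < b; ++v) {
                        // middle bases necessarily differ (entries are distinct)
                        if (cross_species(L[u].value, L[v].value))
                            marks.push_back(canonical_code64(L[u].code, k));
                        if (cross_species(L[v].value, L[u].value))
                            marks.push_back(canonical_code64(L[v].code, k));
                    }
                a = b;
            }
            i = j;
        }
    }
    // (4) transfer weak bits to the canonical entries in the table
    std::sort(marks.begin(), marks.end());
    marks.erase(std::unique(marks.begin(), marks.end()), marks.end());
    for (uint64_t m : marks) st->set_weak(m);
    return (double)marks.size();
}

// Direct 3k-neighbor enumeration (the reference annotation used for
// cross-checking the chunked algorithm).
// [[Rcpp::export(name = ".cpp_mark_weak_bruteforce")]]
double cpp_mark_weak_bruteforce(SEXP sp) {
    StorePtr st(sp);
    int k = st->k;
    std::vector<uint64_t> marks;
    for (uint64_t f = 0; f < st->p; ++f) {
        for (int j = 0; j < CuckooStore::B; ++j) {
            int c = st->slot_choice(f, j);
            if (c == 0) break;
            int v = st->slot_value(f, j) & 3;
            if (v != 1 && v != 2) continue;
            uint64_t key = st->reconstruct(c - 1, f, st->slot_quot(f, j));
            bool weak = false;
            for (int pos = 0; pos < k && !weak; ++pos) {
                uint64_t base = (key >> (2 * pos)) & 3ULL;
                for (uint64_t alt = 0; alt < 4 && !weak; ++alt) {
                    if (alt == base) continue;
                    uint64_t nb = (key & ~(3ULL << (2 * pos))) | (alt << (2 * pos));
                    int nv = st->lookup(canonical_code64(nb, k));
                    if (nv > 0 && cross_species(v, nv & 3)) weak = true;
                }
            }
            if (weak) marks.push_back(key);
        }
    }
    for (uint64_t m : marks) st->set_weak(m);
    return (double)marks.size();
}
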