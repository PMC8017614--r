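#include "xenosort_types.h"
#include <cstdio>
#include <cstring>
using namespace Rcpp;

typedef XPtr<CuckooStore> StorePtr;

// [[Rcpp::export(name = ".cpp_store_new")]]
SEXP cpp_store_new(double expected_keys, double target_load, int k,
                   double seed, int shortcut_mode, int prefetch_level,
                   int max_walk, int walk_retries) {
    if (expected_keys < 1) stop("expected_keys must be >= 1");
    if (target_load <= 0 || target_load > 0.999)
        stop("target_load must be in (0, 0.999]");
    uint64_t p = (uint64_t)std::ceil(expected_keys / (CuckooStore::B * target_load));
    if (p < 1) p = 1;
    CuckooStore *st = new CuckooStore();
    st->init(k, p, target_load, (uint64_t)seed, shortcut_mode, prefetch_level,
             max_walk, walk_retries);
    return StorePtr(st, true);
}

// [[Rcpp::export(name = ".cpp_store_params")]]
List cpp_store_params(SEXP sp) {
    StorePtr st(sp);
    NumericVector a(3), b(3);
    for (int i = 0; i < 3; ++i) { a[i] = (double)st->A[i]; b[i] = (double)st->Boff[i]; }
    return List::create(
        _["k"] = st->k, _["h"] = CuckooStore::H, _["b"] = CuckooStore::B,
        _["p"] = (double)st->p, _["capacity"] = (double)(st->p * CuckooStore::B),
        _["target_load"] = st->target_load, _["seed"] = (double)st->seed,
        _["shortcut_mode"] = st->shortcut_mode, _["prefetch_level"] = st->prefetch_level,
        _["max_walk"] = st->max_walk, _["walk_retries"] = st->walk_retries,
        _["qbits"] = st->qbits,
        _["slot_bits"] = st->slotbits, _["n_keys"] = (double)st->nkeys,
        _["load"] = st->p ? (double)st->nkeys / (double)(st->p * CuckooStore::B) : 0.0,
        _["hash_a"] = a, _["hash_b"] = b);
}

// [[Rcpp::export(name = ".cpp_store_set_mode")]]
void cpp_store_set_mode(SEXP sp, int shortcut_mode, int prefetch_level) {
    StorePtr st(sp);
    st->shortcut_mode = shortcut_mode;
    st->prefetch_level = prefetch_level;
}

// Insert keys with values; returns number inserted before any failure and a
// failure flag (walk exceeded).  Values must be 1, 2 or 3.
// [[Rcpp::export(name = ".cpp_store_insert")]]
List cpp_store_insert(SEXP sp, NumericVector keys, IntegerVector values) {
    StorePtr st(sp);
    if (values.size() != keys.size() && values.size() != 1)
        stop("values must have length 1 or length(keys)");
    R_xlen_t n = keys.size();
    R_xlen_t done = 0;
    bool failed = false;
    for (R_xlen_t i = 0; i < n; ++i) {
        int v = values.size() == 1 ? values[0] : values[i];
        if (v < 1 || v > 3) stop("species value must be 1 (host), 2 (graft) or 3 (both)");
        uint64_t x = (uint64_t)keys[i];
        if (x > st->mask) stop("key exceeds 4^k - 1");
        int r = st->insert(x, v);
        if (r == -1) { failed = true; break; }
        ++done;
    }
    return List::create(_["inserted"] = (double)done, _["failed"] = failed);
}

// [[Rcpp::export(name = ".cpp_store_lookup")]]
IntegerVector cpp_store_lookup(SEXP sp, NumericVector keys) {
    StorePtr st(sp);
    R_xlen_t n = keys.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        int v = st->lookup((uint64_t)keys[i]);
        out[i] = v < 0 ? NA_INTEGER : v;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_store_probe_counts")]]
IntegerVector cpp_store_probe_counts(SEXP sp, NumericVector keys) {
    StorePtr st(sp);
    R_xlen_t n = keys.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        int probes = 0;
        st->lookup((uint64_t)keys[i], &probes);
        out[i] = probes;
    }
    return out;
}

// [[Rcpp::export(name = ".cpp_store_set_weak")]]
IntegerVector cpp_store_set_weak(SEXP sp, NumericVector keys) {
    StorePtr st(sp);
    R_xlen_t n = keys.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        int r = st->set_weak((uint64_t)keys[i]);
        if (r == -2) stop("set_weak: key not present in store");
        if (r == -3) stop("set_weak: key has value 'both'; weak bit applies only to exclusive k-mers");
        out[i] = r;
    }
    return out;
}

// Full scan: reconstructed canonical keys, values, resting choices, buckets.
// [[Rcpp::export(name = ".cpp_store_entries")]]
List cpp_store_entries(SEXP sp) {
    StorePtr st(sp);
    std::vector<double> keys, buckets;
    std::vector<int> values, choices;
    keys.reserve(st->nkeys);
    for (uint64_t f = 0; f < st->p; ++f) {
        for (int j = 0; j < CuckooStore::B; ++j) {
            int c = st->slot_choice(f, j);
            if (c == 0) break;  // occupied slots form a prefix of the bucket
            keys.push_back((double)st->reconstruct(c - 1, f, st->slot_quot(f, j)));
            values.push_back(st->slot_value(f, j));
            choices.push_back(c);
            buckets.push_back((double)f);
        }
    }
    return List::create(_["key"] = wrap(keys), _["value"] = wrap(values),
                        _["choice"] = wrap(choices), _["bucket"] = wrap(buckets));
}

// Per-bucket empty-slot counts and shortcut bits (for layout diagnostics).
// [[Rcpp::export(name = ".cpp_store_bucket_fill")]]
List cpp_store_bucket_fill(SEXP sp) {
    StorePtr st(sp);
    IntegerVector occ((R_xlen_t)st->p), sb((R_xlen_t)st->p);
    for (uint64_t f = 0; f < st->p; ++f) {
        int n = 0;
        for (int j = 0; j < CuckooStore::B; ++j)
            if (st->slot_choice(f, j) != 0) ++n;
        occ[(R_xlen_t)f] = n;
        sb[(R_xlen_t)f] = st->bucket_sbits(f);
    }
    return List::create(_["occupied"] = occ, _["shortcut_bits"] = sb);
}

// [[Rcpp::export(name = ".cpp_store_fill_stats")]]
List cpp_store_fill_stats(SEXP sp) {
    StorePtr st(sp);
    if (st->nkeys == 0) stop("fill statistics undefined for an empty store");
    double byc[3] = {0, 0, 0};
    double byval[8] = {0, 0, 0, 0, 0, 0, 0, 0};
    for (uint64_t f = 0; f < st->p; ++f)
        for (int j = 0; j < CuckooStore::B; ++j) {
            int c = st->slot_choice(f, j);
            if (c == 0) break;
            byc[c - 1] += 1;
            byval[st->slot_value(f, j)] += 1;
        }
    double tot = byc[0] + byc[1] + byc[2];
    NumericVector frac = NumericVector::create(byc[0] / tot, byc[1] / tot, byc[2] / tot);
    double mean_probes = 1 * frac[0] + 2 * frac[1] + 3 * frac[2];
    NumericVector vcounts(8);
    for (int i = 0; i < 8; ++i) vcounts[i] = byval[i];
    return List::create(
        _["load"] = tot / (double)(st->p * CuckooStore::B),
        _["choice_fractions"] = frac,
        _["mean_probes_present"] = mean_probes,
        _["value_counts"] = vcounts,
        _["n_keys"] = tot);
}

// ---- serialization (little-endian custom binary format) -------------------
static const char MAGIC[8] = {'X', 'S', 'O', 'R', 'T', 'I', 'X', '1'};
static const uint32_t FORMAT_VERSION = 1;

template <typename T> static void wr(FILE *f, const T &v) {
    if (fwrite(&v, sizeof(T), 1, f) != 1) { fclose(f); stop("write error"); }
}
template <typename T> static void rd(FILE *f, T *v) {
    if (fread(v, sizeof(T), 1, f) != 1) { fclose(f); stop("index file truncated"); }
}

// [[Rcpp::export(name = ".cpp_store_save")]]
void cpp_store_save(SEXP sp, std::string path) {
    StorePtr st(sp);
    FILE *f = fopen(path.c_str(), "wb");
    if (!f) stop("cannot open '%s' for writing", path.c_str());
    if (fwrite(MAGIC, 1, 8, f) != 8) { fclose(f); stop("write error"); }
    wr(f, FORMAT_VERSION);
    int32_t k = st->k, h = CuckooStore::H, b = CuckooStore::B;
    wr(f, k); wr(f, h); wr(f, b);
    uint64_t p = st->p; wr(f, p);
    wr(f, st->target_load);
    uint64_t seed = st->seed; wr(f, seed);
    int32_t sm = st->shortcut_mode, pl = st->prefetch_level, mw = st->max_walk;
    int32_t wrt = st->walk_retries;
    wr(f, sm); wr(f, pl); wr(f, mw); wr(f, wrt);
    for (int i = 0; i < 3; ++i) { wr(f, st->A[i]); }
    for (int i = 0; i < 3; ++i) { wr(f, st->Boff[i]); }
    wr(f, st->nkeys);
    int32_t qb = st->qbits; wr(f, qb);
    uint64_t ns = st->slots.size(); wr(f, ns);
    if (ns && fwrite(st->slots.data(), 1, ns, f) != ns) { fclose(f); stop("write error"); }
    uint64_t nb = st->sbits.size(); wr(f, nb);
    if (nb && fwrite(st->sbits.data(), 1, nb, f) != nb) { fclose(f); stop("write error"); }
    fclose(f);
}

// [[Rcpp::export(name = ".cpp_store_load")]]
SEXP cpp_store_load(std::string path) {
    FILE *f = fopen(path.c_str(), "rb");
    if (!f) stop("cannot open '%s'", path.c_str());
    char magic[8];
    if (fread(magic, 1, 8, f) != 8 || memcmp(magic, MAGIC, 8) != 0) {
        fclose(f); stop("not a xenosort index file (bad magic)");
    }
    uint32_t ver; rd(f, &ver);
    if (ver != FORMAT_VERSION) { fclose(f); stop("unsupported index format version %d", (int)ver); }
    int32_t k, h, b; rd(f, &k); rd(f, &h); rd(f, &b);
    if (h != CuckooStore::H || b != CuckooStore::B) { fclose(f); stop("unsupported (h,b) configuration"); }
    uint64_t p; rd(f, &p);
    double load; rd(f, &load);
    uint64_t seed; rd(f, &seed);
    int32_t sm, pl, mw, wrt; rd(f, &sm); rd(f, &pl); rd(f, &mw); rd(f, &wrt);
    CuckooStore *st = new CuckooStore();
    st->init(k, p, load, seed, sm, pl, mw, wrt);
    for (int i = 0; i < 3; ++i) rd(f, &st->A[i]);
    for (int i = 0; i < 3; ++i) rd(f, &st->Boff[i]);
    for (int i = 0; i < 3; ++i) st->Ainv[i] = odd_inverse(st->A[i], st->mask);
    rd(f, &st->nkeys);
    int32_t qb; rd(f, &qb);
    if (qb != st->qbits) { delete st; fclose(f); stop("index file inconsistent (quotient width)"); }
    uint64_t ns; rd(f, &ns);
    if (ns != st->slots.size()) { delete st; fclose(f); stop("index file inconsistent (slot array size)"); }
    if (ns && fread(st->slots.data(), 1, ns, f) != ns) { delete st; fclose(f); stop("index file truncated"); }
    uint64_t nb; rd(f, &nb);
    if (nb != st->sbits.size()) { delete st; fclose(f); stop("index file inconsistent (shortcut array size)"); }
    if (nb && fread(st->sbits.data(), 1, nb, f) != nb) { delete st; fclose(f); stop("index file truncated"); }
    fclose(f);
    return StorePtr(st, true);
}
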