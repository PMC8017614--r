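#ifndef XENOSORT_TYPES_H
#define XENOSORT_TYPES_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <random>
#include <algorithm>
#include <string>

// ---- base encoding -------------------------------------------------------
// A=0, C=1, G=2, T/U=3; anything else (incl. N) is invalid (-1).
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

static inline char code_base(int b) {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    return B[b & 3];
}

// reverse complement of a 2k-bit code (complement = 3 - digit, reverse digits)
static inline uint64_t revcomp_code64(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return r;
}

static inline uint64_t canonical_code64(uint64_t x, int k) {
    uint64_t r = revcomp_code64(x, k);
    return x > r ? x : r;
}

// ---- bit-packed array helpers (LSB-first within the byte stream) ---------
static inline uint64_t bits_get(const uint8_t *d, uint64_t pos, int w) {
    uint64_t r = 0;
    int got = 0;
    uint64_t byte = pos >> 3;
    int off = (int)(pos & 7);
    while (got < w) {
        int take = 8 - off;
        if (take > w - got) take = w - got;
        uint64_t chunk = ((uint64_t)d[byte] >> off) & ((1ULL << take) - 1ULL);
        r |= chunk << got;
        got += take;
        off = 0;
        ++byte;
    }
    return r;
}

static inline void bits_set(uint8_t *d, uint64_t pos, int w, uint64_t v) {
    int put = 0;
    uint64_t byte = pos >> 3;
    int off = (int)(pos & 7);
    while (put < w) {
        int take = 8 - off;
        if (take > w - put) take = w - put;
        uint8_t m = (uint8_t)(((1u << take) - 1u) << off);
        d[byte] = (uint8_t)((d[byte] & ~m) | (((v >> put) & ((1ULL << take) - 1ULL)) << off));
        put += take;
        off = 0;
        ++byte;
    }
}

// multiplicative inverse of odd a modulo 2^(2k), by Newton iteration
static inline uint64_t odd_inverse(uint64_t a, uint64_t mask) {
    uint64_t x = a;          // correct to 3 bits
    for (int i = 0; i < 6; ++i) x *= 2ULL - a * x; // doubles precision each step
    return x & mask;
}

// ---- the (3,4)-bucketed quotiented Cuckoo store ---------------------------
// Species values: 1 host, 2 graft, 3 both, 5 weak host, 6 weak graft.
// Slot record (bit-packed): 2-bit choice tag (0 = empty), 3-bit value,
// qbits-bit quotient.  Shortcut bits: 2 per bucket (bit1: an element with
// first choice here rests at its second choice; bit2: an element with first
// or second choice here rests at its third choice).
class CuckooStore {
public:
    static constexpr int H = 3, B = 4;
    int k;
    uint64_t p;              // bucket count
    double target_load;
    uint64_t seed;
    int shortcut_mode;       // 0, 1, 2 (lookup-time interpretation only)
    int prefetch_level;      // advisory; results invariant
    int max_walk;
    int walk_retries;        // fresh-randomness walk restarts after rollback
    uint64_t A[3], Boff[3], Ainv[3];
    int qbits, slotbits;
    uint64_t mask;           // 4^k - 1
    std::vector<uint8_t> slots;
    std::vector<uint8_t> sbits;
    uint64_t nkeys;
    std::mt19937_64 rng;

    CuckooStore() : k(0), p(0), target_load(0), seed(0), shortcut_mode(2),
                    prefetch_level(0), max_walk(5000), walk_retries(20),
                    qbits(0), slotbits(0), mask(0), nkeys(0) {}

    void init(int k_, uint64_t p_, double load_, uint64_t seed_,
              int smode, int pflevel, int maxwalk, int retries) {
        if (k_ < 1 || k_ > 31) Rcpp::stop("k must be in 1..31");
        k = k_; p = p_; target_load = load_; seed = seed_;
        shortcut_mode = smode; prefetch_level = pflevel; max_walk = maxwalk;
        walk_retries = retries;
        mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
        qbits = quotient_width(k, p);
        slotbits = 2 + 3 + qbits;
        rng.seed(seed);
        draw_params();
        alloc();
    }

    static int quotient_width(int k_, uint64_t p_) {
        // ceil(2k - log2 p): smallest w with p * 2^w >= 4^k
        unsigned __int128 four_k = (unsigned __int128)1 << (2 * k_);
        if (p_ < 1 || (unsigned __int128)p_ > four_k)
            Rcpp::stop("bucket count p must be in [1, 4^k]");
        int w = 0;
        while (((unsigned __int128)p_ << w) < four_k) ++w;
        return w;
    }

    void draw_params() {
        for (int i = 0; i < H; ++i) {
            for (;;) {
                uint64_t a = (rng() & mask) | 1ULL;
                uint64_t b = rng() & mask;
                bool dup = false;
                for (int j = 0; j < i; ++j)
                    if (A[j] == a && Boff[j] == b) dup = true;
                if (!dup) { A[i] = a; Boff[i] = b; break; }
            }
            Ainv[i] = odd_inverse(A[i], mask);
        }
    }

    void alloc() {
        uint64_t slot_bits_total = (uint64_t)p * B * slotbits;
        slots.assign((slot_bits_total + 7) / 8 + 8, 0);
        sbits.assign((2 * p + 7) / 8 + 8, 0);
        nkeys = 0;
    }

    inline uint64_t rot_half(uint64_t x) const {
        if (k == 0) return x;
        return ((x << k) | (x >> k)) & mask;
    }
    inline uint64_t ghash(uint64_t x, int i) const {
        return (A[i] * (rot_half(x) ^ Boff[i])) & mask;
    }
    inline uint64_t ginv(uint64_t y, int i) const {
        return rot_half(((Ainv[i] * y) & mask) ^ Boff[i]);
    }
    inline uint64_t reconstruct(int choice0, uint64_t f, uint64_t q) const {
        return ginv(p * q + f, choice0);
    }

    // slot accessors
    inline uint64_t slot_pos(uint64_t bucket, int j) const {
        return ((uint64_t)bucket * B + j) * (uint64_t)slotbits;
    }
    inline int slot_choice(uint64_t bucket, int j) const {
        return (int)bits_get(slots.data(), slot_pos(bucket, j), 2);
    }
    inline int slot_value(uint64_t bucket, int j) const {
        return (int)bits_get(slots.data(), slot_pos(bucket, j) + 2, 3);
    }
    inline uint64_t slot_quot(uint64_t bucket, int j) const {
        return qbits ? bits_get(slots.data(), slot_pos(bucket, j) + 5, qbits) : 0;
    }
    inline void slot_write(uint64_t bucket, int j, int choice, int value, uint64_t q) {
        uint64_t pos = slot_pos(bucket, j);
        bits_set(slots.data(), pos, 2, (uint64_t)choice);
        bits_set(slots.data(), pos + 2, 3, (uint64_t)value);
        if (qbits) bits_set(slots.data(), pos + 5, qbits, q);
    }
    inline void slot_set_value(uint64_t bucket, int j, int value) {
        bits_set(slots.data(), slot_pos(bucket, j) + 2, 3, (uint64_t)value);
    }
    inline int bucket_sbits(uint64_t bucket) const {
        return (int)bits_get(sbits.data(), 2 * bucket, 2);
    }
    inline void bucket_set_sbit(uint64_t bucket, int which) { // which: 0 -> bit1, 1 -> bit2
        uint64_t pos = 2 * bucket + which;
        bits_set(sbits.data(), pos, 1, 1ULL);
    }

    // set shortcut bits on earlier-choice buckets after key rests at choice ci (0-based)
    void note_resting_choice(uint64_t x, int ci) {
        if (ci >= 1) {
            uint64_t f1 = ghash(x, 0) % p;
            if (ci == 1) bucket_set_sbit(f1, 0);
            else { // ci == 2
                bucket_set_sbit(f1, 1);
                uint64_t f2 = ghash(x, 1) % p;
                bucket_set_sbit(f2, 1);
            }
        }
    }

    // lookup; returns value or -1; *probes (optional) counts buckets examined
    int lookup(uint64_t x, int *probes = 0) const {
        bool skip2 = false;
        for (int i = 0; i < H; ++i) {
            if (i == 1 && skip2) continue;
            uint64_t g = ghash(x, i), f = g % p, q = g / p;
            if (probes) ++*probes;
            for (int j = 0; j < B; ++j) {
                int c = slot_choice(f, j);
                if (c == 0) return -1;       // tight layout: empty slot ends search
                if (c == i + 1 && slot_quot(f, j) == q)
                    return slot_value(f, j);
            }
            if (i == H - 1) break;
            if (shortcut_mode == 1) {
                if (bucket_sbits(f) == 0) return -1;
            } else if (shortcut_mode == 2) {
                int sb = bucket_sbits(f);
                if (i == 0) {
                    bool b1 = sb & 1, b2 = sb & 2;
                    if (!b1 && !b2) return -1;
                    if (!b1) skip2 = true;   // only a third-choice resident is possible
                } else { // i == 1
                    if (!(sb & 2)) return -1;
                }
            }
        }
        return -1;
    }

    // locate a present key; returns true and fills (bucket, slot)
    bool locate(uint64_t x, uint64_t *bucket, int *slot) const {
        for (int i = 0; i < H; ++i) {
            uint64_t g = ghash(x, i), f = g % p, q = g / p;
            for (int j = 0; j < B; ++j) {
                int c = slot_choice(f, j);
                if (c == 0) return false;
                if (c == i + 1 && slot_quot(f, j) == q) {
                    *bucket = f; *slot = j; return true;
                }
            }
        }
        return false;
    }

    static int combine_values(int oldv, int newv) {
        if (oldv == newv) return oldv;
        return 3; // host + graft (either order), or anything with both
    }

    bool try_place_free(uint64_t x, int value) {
        for (int i = 0; i < H; ++i) {
            uint64_t g = ghash(x, i), f = g % p, q = g / p;
            for (int j = 0; j < B; ++j) {
                if (slot_choice(f, j) == 0) {
                    slot_write(f, j, i + 1, value, q);
                    note_resting_choice(x, i);
                    return true;
                }
            }
        }
        return false;
    }

    // returns 0 inserted, 1 value combined (key present), -1 walk too long
    int insert(uint64_t x, int value) {
        uint64_t f; int j;
        if (locate(x, &f, &j)) {
            int oldv = slot_value(f, j);
            if (oldv > 3 || value > 3)
                Rcpp::stop("insert: weak-flagged values are not allowed during build");
            slot_set_value(f, j, combine_values(oldv, value));
            return 1;
        }
        if (try_place_free(x, value)) { ++nkeys; return 0; }
        std::uniform_int_distribution<int> pick(0, H * B - 1);
        struct Move { uint64_t bucket; int slot; int choice; int value; uint64_t quot; };
        std::vector<Move> moves;
        for (int attempt = 0; attempt <= walk_retries; ++attempt) {
            uint64_t cur = x; int curval = value;
            uint64_t prev_bucket = 0; int prev_slot = -1;
            moves.clear();
            for (int steps = 0; steps < max_walk; ++steps) {
                // uniform victim among the hb slots, excluding the slot just
                // filled (a non-backtracking walk never undoes the last move)
                int r, ci, sj;
                uint64_t g, fb, q;
                do {
                    r = pick(rng);
                    ci = r / B; sj = r % B;
                    g = ghash(cur, ci); fb = g % p; q = g / p;
                } while (prev_slot >= 0 && fb == prev_bucket && sj == prev_slot);
                int vc = slot_choice(fb, sj);
                int vv = slot_value(fb, sj);
                uint64_t vq = slot_quot(fb, sj);
                uint64_t victim = reconstruct(vc - 1, fb, vq);
                moves.push_back(Move{fb, sj, vc, vv, vq});
                slot_write(fb, sj, ci + 1, curval, q);
                note_resting_choice(cur, ci);
                prev_bucket = fb; prev_slot = sj;
                cur = victim; curval = vv;
                if (try_place_free(cur, curval)) { ++nkeys; return 0; }
            }
            // walk too long: roll the table back and retry with fresh
            // randomness (shortcut bits stay set; they only over-approximate)
            for (size_t m = moves.size(); m-- > 0; )
                slot_write(moves[m].bucket, moves[m].slot, moves[m].choice,
                           moves[m].value, moves[m].quot);
        }
        return -1; // table too full at this walk length
    }

    // -2 absent, -3 value 'both', 0 ok (idempotent)
    int set_weak(uint64_t x) {
        uint64_t f; int j;
        if (!locate(x, &f, &j)) return -2;
        int v = slot_value(f, j);
        if (v == 3) return -3;
        if (v == 1 || v == 2) slot_set_value(f, j, v | 4);
        return 0;
    }
};

#endif
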