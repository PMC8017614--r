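---
title: "Alignment-free xenograft read sorting: model, data structure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free xenograft read sorting: model, data structure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenosort)
```

## The problem

Sequencing a xenograft sample — for instance a patient-derived human tumor
grown in a mouse — yields a mixture of reads from the graft (human) and the
host (mouse). Downstream tumor analyses want the graft reads only; variant
calls in particular are easily contaminated by host reads that align
passably to the human genome. `xenosort` separates such mixtures without
aligning anything: it looks up every k-mer of every fragment in a
precomputed key-value store that knows, for each k-mer of either reference,
which species it occurs in, and then applies a decision rule to the
per-fragment k-mer category counts.

## Canonical k-mer codes

A k-mer is encoded in base 4 (A=0, C=1, G=2, T/U=3, most significant digit
first); `AGCG` becomes 38 and its reverse complement `CGCT` becomes 103.
Because a read can come from either strand, a k-mer and its reverse
complement must map to the same key: the *canonical code* is the maximum of
the two encodings (103 for the example). We use odd k only in the index —
then no k-mer equals its own reverse complement, there are exactly `4^k/2`
canonical codes, and every k-mer has a well-defined middle base, which the
weak-k-mer annotation below exploits. The default is k = 25, a good
compromise between species specificity and memory; each sequencing error
corrupts up to k of a read's k-mers, which argues against much larger k.

Every k-mer in the index carries a 3-bit species value: host (1), graft
(2), both (3), weak host (5), weak graft (6) — "weak" flags an exclusive
k-mer whose single-nucleotide neighbor occurs in the other species.

## The store: (3,4)-bucketed Cuckoo hashing with quotienting

The store is a bucketed Cuckoo hash table with h = 3 hash functions and
b = 4 slots per bucket. Each key can live in one of three buckets; each
bucket access is one random memory access. This geometry supports loads
beyond 99.9% in the limit, but the package (like the tool it models) fills
tables to 88% by default, so that 76–77% of keys are found at their first
bucket and a present-key lookup costs about 1.31 bucket accesses on
average.

The bucket-address functions have the form `f(x) = g(x) mod p` where
`g(x) = (a * (rot(x) XOR b)) mod 4^k`, `rot` swaps the two k-bit halves of
the code, `a` is a random odd multiplier and `b` a random offset. Because
`a` is odd, `g` is a bijection with an explicit inverse (multiply by the
inverse of `a` modulo `4^k`, XOR, rotate). Bijectivity buys *quotienting*:
instead of the full 2k-bit key we store only the quotient
`q(x) = g(x) %/% p` — the bucket index `f(x)` supplies the remainder, and
`(f, q)` reconstructs the key exactly. A slot therefore holds
`2 + 3 + ceiling(2k - log2 p)` bits: a 2-bit tag saying which hash function
placed the key (0 = empty slot), the 3-bit value, and the quotient. For
k = 25 and p = 1,276,595,745 that is 25 bits per k-mer, 100 bits per
bucket. Slots are bit-packed contiguously; buckets are not padded to cache
lines (the same space/speed trade the original design makes).

### Insertion and the random walk

Keys are inserted at the first free slot among their three buckets, in
choice order. If all 12 candidate slots are occupied, a uniformly random
one of them is evicted and re-inserted the same way ("random walk"). Two
details are deliberate choices where the procedure is underdetermined:

* the victim draw excludes the slot written in the immediately preceding
  step, so a walk never immediately undoes its last move;
* a walk that exceeds `max_walk` (default 5000) evictions is **rolled back
  exactly** (every displaced key is restored from a move log) and retried
  with fresh randomness, up to `walk_retries` (default 20) times. This is
  the per-insertion analogue of restarting construction with a new random
  seed, and it matters near the load limit, where individual walk lengths
  are heavy-tailed even though the table is fillable.

If retries are exhausted the insertion reports failure and the caller
rebuilds with a larger table or a different seed (`build_index` retries
with an incremented seed automatically). Working at 99.9% load one is at
the edge of the (3,4) geometry's orientability: experiments with a complete
(breadth-first augmenting) placement search show that a few in ten random
instances of 10^5 slots filled to exactly 99.9% admit *no* valid placement
at all. Restarting with fresh hash functions, as the failure contract
prescribes, resolves exactly those cases; the walk itself was observed to
reach the feasibility optimum whenever it existed.

Two invariants of this construction are load-bearing and tested: the
occupied slots of a bucket form a prefix, and the layout is *tight* — no
stored key could be moved to an earlier-choice bucket with a free slot.
Tightness holds because free slots are only ever consumed, never created
(there is no deletion, by contract), and every placement checks earlier
choices first.

### Fast unsuccessful lookups

Absent k-mers (roughly half of all lookups for a mixed sample, and nearly
all for contaminant reads) would naively cost three bucket reads. Three
mechanisms cut this short, none of which may ever change a lookup result,
only its cost — the suite verifies result-invariance and monotone probe
counts across modes:

* **empty-slot rule** (always on): if a probed bucket has a free slot, the
  tight layout guarantees the key is in no later bucket;
* **mode 1**: one flag bit per bucket records "some key that wanted this
  bucket lives at a later choice"; if clear, an unsuccessful search stops;
* **mode 2**: two bits separate "first choice here, stored at second" from
  "first or second choice here, stored at third", allowing the second
  bucket to be skipped entirely when only the third is possible.

The bits are set when a key comes to rest at choice 2 or 3 and are never
cleared — after a rolled-back walk they may over-approximate, which costs
at most extra probes and is sound because keys are never deleted. A
`prefetch_level` parameter (0/1/2) is accepted for interface compatibility
and treated as advisory; this implementation issues no prefetch hints, and
results are invariant by construction.

The 2-bit choice tag and the 3-bit value could be compressed further: with
slots kept in a canonical order a bucket's configuration is one of 35
tuples (6 bits instead of 8) for (h,b) = (3,4), and the four 3-bit values
have 5^4 = 625 joint combinations (10 bits instead of 12). The package
counts these encodings (`count_bucket_configurations`,
`count_value_combinations`) but stores slots uncompressed, trading memory
for decode speed.

## Weak k-mer annotation

A host-exclusive k-mer with a Hamming-distance-1 neighbor attributed to
the graft (graft-exclusive *or* shared) is marked weak, and symmetrically.
(The paper-style definition speaks of a neighbor "in the other species";
we include both-species neighbors since those occur in the other species
too — this is exposed in code as the single place the rule is applied,
`cross_species`.) Scanning all 3k neighbors of every key is quadratic
waste; the production path instead extracts the full list of stored k-mers
*and their reverse complements* with their values, in 16 chunks by the
first two bases (configurable to 1 or 4; the result is chunk-invariant and
tested as such), sorts each chunk, and exploits that for k = 2l+1 a
distance-1 pair differs in its l-suffix, in the l-suffix of its reverse
complement, or in its middle base. Suffix pairs are found inside blocks of
constant (l+1)-prefix with a bit-parallel distance test; prefix pairs are
covered by the reverse complements; middle-base pairs are found by
re-sorting blocks of constant l-prefix with the sort order of middle base
and suffix swapped, which makes them adjacent. Marks are collected and
written back to the canonical entries at the end, so the pass is
idempotent and chunk-order-free. The 3k-neighbor scan is retained as
`mark_weak_bruteforce` and serves as the independent correctness oracle in
the tests (50 random genome pairs, plus a third, all-R re-derivation).

Reference sequences are preprocessed by collapsing runs of more than 25 Ns
to exactly 25 — k-mers containing an N are ignored anyway, so k-mer content
is unchanged, but assemblies padded with megabase N-runs (alternative
alleles kept position-aligned) shrink drastically.

## Fragment classification

For each fragment (read or read pair; mates are summed) the classifier
counts its valid k-mers by category into (h, h', g, g', b, x; n): strong
host, weak host, strong graft, weak graft, both, absent, total. Weighted
scores `S_host = h + floor(h'/2)` and `S_graft = g + floor(g'/2)` halve the
weight of weak evidence; the common threshold is `T = floor(n/4)`.

The rule tree tries cheap decisions first. If one species is entirely
absent (g + g' = 0), the fragment is host if `S_host >= 3`, else both if
`b >= T` (and b > 0), else neither if `x >= 3n/4`, else ambiguous — and
symmetrically. Otherwise: host if g = 0, g' <= 6 and h >= 6 (no strong
opposite evidence, little weak opposite evidence, some strong own
evidence); then the complex rule, host if `S_host >= T`, `g <= 2` and
`4 g' <= S_host`; then both / neither / ambiguous as above. The complex
rule's two constants (opposite-strong cap 2, weak-ratio 4) instantiate
prose that the published appendix pins down elsewhere; they are exposed in
`classify_options()` and tuned for 100–150 bp high-quality short reads.

Three corner cases are package decisions, made once and tested:

* `n = 0` (no valid k-mer, e.g. an all-N read) is *neither* — a literal
  reading of the "both" rule would fire on `b = 0 >= floor(0/4)`;
* for the same reason every "both" rule additionally requires `b > 0`;
* if the host and graft variants of the complex rule fire simultaneously
  (possible only for near-symmetric vectors such as (2,0,2,0,0,4;8)), the
  label is *ambiguous*: any fixed evaluation order would break the
  host/graft symmetry that the rule set is designed to have, and which the
  suite checks on 10^5 fuzzed vectors.

**Quick mode** samples the category of the third and third-last valid
k-mer of each read (2 samples single-end, 4 paired). If all samples agree,
the fragment is labeled from the common category alone (weak host counts
as host, weak graft as graft, absent as neither — the weak/absent mapping
is a package decision); any disagreement, or a read with fewer than three
valid k-mers, falls back to full counting.

## Synthetic data: what it does and does not emulate

The generators build a random host genome, derive a graft by independent
per-base substitutions at a set divergence (optionally keeping a central
block identical, and optionally injecting N-runs), and sample reads with
uniform positions, random strand and independent substitution errors.
Everything is substitution-only — deliberately, since the weak-k-mer model
is itself Hamming-centric. Defaults used across the tests: 2–12 kb
genomes, 1–10% divergence, 100–150 bp reads, 0–1% error, k = 25. Real data
differ in ways these fixtures do not probe: indels, quality-dependent and
context-dependent error profiles, coverage bias, repeats shared between
species at scale, and RNA splicing. A green suite therefore demonstrates
algorithmic correctness (store semantics, annotation, rule tree, I/O
round-trips) and the statistical behavior of the table, not end-to-end
accuracy on real PDX libraries.

Problem sizes were likewise chosen once: the store-vs-oracle equivalence
uses 10^5 present plus 10^5 absent keys; the load-limit experiment fills
10^5 slots to 99.9% for five seeds; the choice-distribution experiment
fills ~10^6 slots to 88% for three seeds, where the first-choice fraction
(expected ≈ 76.7%) and mean probes per present key (≈ 1.31) are stable to
well within the ±2 points / ±0.05 bands used in the checks.

## Numerical and interface notes

* Keys cross the R boundary as doubles; they are exact up to 2^53, so
  per-key R interfaces enforce k <= 26 while index construction and
  classification (which keep keys in C++) support k <= 31.
* R's `runif` has 32-bit granularity; `random_canonical_keys()` combines
  two draws per key. A single-draw generator quietly places keys on a
  2^18-spaced lattice — which degrades the cuckoo graph badly enough to
  make 99%-load builds fail, and is worth a warning to anyone replicating
  the experiments by hand.
* The index file is a little-endian binary container: magic `XSORTIX1`,
  format version, parameters (k, h, b, p, target load, seed, shortcut
  mode, prefetch level, walk limits, the three (a, b) pairs, key count,
  quotient width), then the packed slot array and the shortcut-bit array.
  `run_index` writes build statistics to a JSON sidecar next to it.
* FASTA/FASTQ input and output (gzip transparent) go through Biostrings;
  records pass through classification byte-identically (the `+` separator
  line is normalized to bare `+`).

## Known limitations

Long, high-error reads need different rule constants (`classify_options`
exposes them). Deletion from the store is unsupported by design. The
compressed 6-bit/10-bit bucket encodings are counted but not used for
storage. Multithreading is out of scope; classification is per-fragment
pure, so any chunking of the input yields identical results.
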