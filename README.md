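# xenosort

Alignment-free sorting of xenograft sequencing reads by species of origin.

Sequencing a xenograft sample — typically a patient-derived human tumor
(the **graft**) grown in a mouse (the **host**) — produces a mixture of
reads from both genomes, and host reads routinely contaminate downstream
tumor analyses. `xenosort` separates such mixtures without alignment: it
builds a key-value store over all k-mers of both reference genomes, looks
up every k-mer of every fragment, and classifies each fragment as
`host`, `graft`, `both`, `neither` or `ambiguous` from its k-mer category
counts.

## The method in brief

* **Canonical k-mer codes.** A k-mer is encoded base-4
  (A↦0, C↦1, G↦2, T/U↦3); the canonical code is
  max(code, revcomp-code), so both strands share one key. Odd k (default
  25) gives exactly 4^k/2 canonical codes and a well-defined middle base.
* **(3,4)-bucketed Cuckoo hash store with quotienting.** Each key can
  live in one of h = 3 buckets of b = 4 slots, addressed by
  f_i(x) = g_i(x) mod p with bijective affine g_i(x) = a_i·(rot(x) ⊕ b_i)
  mod 4^k. Only the quotient q_i(x) = g_i(x) ÷ p is stored — (f, q)
  reconstructs the key — so a slot takes 2 + 3 + ⌈2k − log₂ p⌉ bits
  (choice tag, species value, quotient): 25 bits per k-mer at k = 25 and
  p ≈ 1.28·10⁹. Random-walk insertion fills tables to 88% by default
  (loads up to 99.9% are supported), leaving ~76.7% of keys at their
  first choice, ~1.31 bucket probes per present key. Tight-layout and
  shortcut-bit rules terminate unsuccessful lookups early without ever
  changing a result.
* **Weak k-mers.** A host- or graft-exclusive k-mer with a
  Hamming-distance-1 neighbor attributed to the other species is flagged
  "weak" (values 5/6 instead of 1/2) by a chunked extract–sort–scan pass
  over all stored k-mers and their reverse complements.
* **Rule-tree classification.** Per fragment (mates summed) the counts
  (h, h′, g, g′, b, x; n) feed a hierarchy of rules built on
  S_host = h + ⌊h′/2⌋, S_graft = g + ⌊g′/2⌋ and T = ⌊n/4⌋; a quick mode
  samples just the 3rd and 3rd-last k-mer of each read and falls back to
  full counting on disagreement.

## Worked example

```r
library(xenosort)
dir <- tempfile(); dir.create(dir)

# synthetic mouse/human stand-ins: 6 kb, 8% divergence
gp <- make_genome_pair(6000, divergence = 0.08, seed = 11)
write_fasta(c(mouse_chr = gp$host),  file.path(dir, "host.fa"))
write_fasta(c(human_chr = gp$graft), file.path(dir, "graft.fa"))

idx <- run_index(file.path(dir, "host.fa"), file.path(dir, "graft.fa"),
                 k = 25, seed = 1, out_path = file.path(dir, "pdx.xsx"))
#> index: 11014 k-mers at load 0.807 written to .../pdx.xsx
print(idx)
#> xenosort k-mer index: k=25, 11,014 k-mers, load 0.807, weak-marked: TRUE
#>    host=3297  graft=3297  both=938  weak_host=1741  weak_graft=1741

# a labeled 500-fragment sample: 150 host reads, 350 graft reads, 1% error
rs <- make_read_set(list(host = gp$host, graft = gp$graft), c(150, 350),
                    read_len = 120, error_rate = 0.01, seed = 2)
write_read_set(rs, file.path(dir, "sample"))

rep <- run_sort(file.path(dir, "pdx.xsx"), file.path(dir, "sample.fq"),
                out_prefix = file.path(dir, "sorted"))
#> sorted 500 fragments into .../sorted-{host,graft,both,neither,ambiguous}.fq
rep
#>       label count percent
#> 1      host   150      30
#> 2     graft   350      70
#> 3      both     0       0
#> 4   neither     0       0
#> 5 ambiguous     0       0

table(truth = rs$label, call = attr(rep, "labels"))
#>        call
#> truth   host graft both neither ambiguous
#>   graft    0   350    0       0         0
#>   host   150     0    0       0         0
```

The index report lists stored k-mers per species value; `host=3297,
graft=3297` are the exclusive k-mers, `both=938` occur in either genome
(here: by chance plus conserved stretches), and the `weak_*` counts are
exclusive k-mers one substitution away from the other species. The sort
writes five FASTQ files and a count report; on this error-containing but
strongly diverged sample every fragment is recovered correctly.

A thin CLI wraps the same functions:

```sh
exec/xenosortr index --host host.fa --graft graft.fa -k 25 --seed 1 --out pdx.xsx
exec/xenosortr classify --index pdx.xsx --fastq R1.fq --pairs R2.fq \
    --mode sort --out sorted --compress
```

## Package layout

| Piece | Purpose |
|---|---|
| `encode_kmer`, `canonical_code`, `canonical_kmers` | base-4 encoding, canonicalization, windowed iteration |
| `g_forward` / `g_inverse`, `quotient_bits` | bijective affine hashing and quotient arithmetic |
| `cuckoo_new` / `cuckoo_insert` / `cuckoo_lookup` … | the bit-packed (3,4) Cuckoo store, fill statistics, serialization |
| `build_index`, `mark_weak`(`_bruteforce`) | index construction and weak-k-mer annotation |
| `fragment_stats`, `classify_stats`, `classify_fragments` | per-fragment counts and the rule tree (plus quick mode) |
| `run_index`, `run_count`, `run_sort` | FASTA/FASTQ drivers (gzip transparent) |
| `make_genome_pair`, `make_read_set`, `random_canonical_keys` | synthetic genomes, labeled reads, random keys |

See `vignettes/xenosort-methods.Rmd` for the model, the design decisions
and their rationale, and known limitations.
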