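Package: xenosort
Title: Alignment-Free Sorting of Xenograft Sequencing Reads by Species of Origin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies sequencing fragments from xenograft experiments
    (e.g. patient-derived tumor tissue grown in mouse) as host, graft,
    both, neither or ambiguous, without alignment. A key-value store of
    canonical k-mers maps each k-mer of the host and graft references to
    its species of origin; the store is a three-way bucketed Cuckoo hash
    table with quotienting, supporting load factors above 99.9% at a few
    bits per k-mer. Host- or graft-exclusive k-mers with a
    Hamming-distance-1 neighbor in the other species are annotated as
    weak, and fragments are classified from per-fragment k-mer category
    counts by a hierarchical rule tree. Includes index construction from
    FASTA references, FASTQ classification (count and five-way sort),
    and a synthetic read-set generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
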