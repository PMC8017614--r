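test_that("genome pair generation is seeded and respects divergence", {
  gp1 <- make_genome_pair(2000, divergence = 0.05, seed = 1)
  gp2 <- make_genome_pair(2000, divergence = 0.05, seed = 1)
  expect_identical(gp1, gp2)                       # byte-identical reruns
  expect_false(identical(gp1, make_genome_pair(2000, divergence = 0.05, seed = 2)))
  gp0 <- make_genome_pair(2000, divergence = 0, seed = 3)
  expect_identical(gp0$host, gp0$graft)            # divergence 0
  # per-position substitution at rate 1 outside shared block
  gp <- make_genome_pair(10000, divergence = 1, seed = 4)
  h <- strsplit(gp$host, "")[[1]]; g <- strsplit(gp$graft, "")[[1]]
  expect_equal(sum(h == g), 0)
  # k-mer overlap near zero at full divergence
  shared <- intersect(canonical_kmers(gp$host, 25)$code,
                      canonical_kmers(gp$graft, 25)$code)
  expect_lt(length(shared), 5)
  # shared block stays identical
  gps <- make_genome_pair(2000, divergence = 1, shared_fraction = 0.3, seed = 5)
  r <- gps$shared_range
  expect_identical(substr(gps$host, r["start"] + 1, r["end"]),
                   substr(gps$graft, r["start"] + 1, r["end"]))
  # N-run injection
  gpn <- make_genome_pair(500, seed = 6, n_run = 40)
  expect_true(grepl("N{40}", gpn$host))
})

test_that("read simulation is seeded, strand-aware and error-calibrated", {
  g <- make_genome_pair(3000, seed = 7)$host
  r1 <- make_reads(g, 100, read_len = 100, error_rate = 0, seed = 8)
  r2 <- make_reads(g, 100, read_len = 100, error_rate = 0, seed = 8)
  expect_identical(r1, r2)
  # error-free reads map back exactly (forward or reverse complement)
  plus <- r1$reads1[r1$strand == "+"]
  starts <- r1$pos[r1$strand == "+"]
  expect_equal(plus, substring(g, starts + 1, starts + 100))
  # error rate roughly calibrated
  re <- make_reads(g, 200, read_len = 100, error_rate = 0.05, seed = 9)
  ref <- substring(g, re$pos + 1, re$pos + 100)
  rc_sel <- re$strand == "-"
  obs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, re$reads1[!rc_sel], ref[!rc_sel])
  expect_gt(mean(obs) / 100, 0.03)
  expect_lt(mean(obs) / 100, 0.07)
})

test_that("error-free host reads consist of indexed host-side k-mers", {
  gp <- make_genome_pair(4000, divergence = 0.08, seed = 10)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 11)
  mark_weak(idx)
  rs <- make_reads(gp$host, 50, read_len = 120, error_rate = 0, seed = 12)
  vals <- unlist(lapply(rs$reads1, function(r) {
    cuckoo_lookup(idx$store, canonical_kmers(r, 25)$code)
  }))
  expect_false(any(is.na(vals)))                   # every k-mer indexed
  expect_true(all(vals %in% c(1, 3, 5)))           # host, both or weak host
})

test_that("end-to-end recovery holds at 5% divergence and 1% error", {
  gp <- make_genome_pair(12000, divergence = 0.05, seed = 13)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 14)
  mark_weak(idx)
  rs <- make_read_set(list(host = gp$host, graft = gp$graft), 500,
                      read_len = 150, error_rate = 0.01, seed = 15)
  lab <- as.character(classify_fragments(idx, rs$reads1))
  host_ok <- mean(lab[rs$label == "host"] %in% c("host", "both"))
  graft_ok <- mean(lab[rs$label == "graft"] %in% c("graft", "both"))
  expect_gte(host_ok, 0.99)
  expect_gte(graft_ok, 0.99)
})

test_that("random canonical keys are distinct, canonical and seeded", {
  ks <- random_canonical_keys(5000, 25, seed = 16)
  expect_equal(length(unique(ks)), 5000)
  expect_equal(canonical_code(ks, 25), ks)         # already canonical
  expect_identical(ks, random_canonical_keys(5000, 25, seed = 16))
  # full 2k-bit entropy: low 18 bits are not all zero (lattice guard)
  expect_gt(length(unique(ks %% 2^18)), 1000)
})
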