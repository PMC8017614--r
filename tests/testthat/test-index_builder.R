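test_that("N-run condensation caps runs without touching k-mer content", {
  expect_equal(condense_n_runs(paste0("A", strrep("N", 100), "C")),
               paste0("A", strrep("N", 25), "C"))
  s <- paste0("A", strrep("N", 10), "C")
  expect_equal(condense_n_runs(s), s)                    # run <= 25 untouched
  expect_equal(condense_n_runs(strrep("N", 26)), strrep("N", 25))
  expect_equal(condense_n_runs("ACGT"), "ACGT")
  # k-mer content identical before and after, many random sequences
  set.seed(3)
  for (i in 1:20) {
    parts <- replicate(4, paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
    s <- paste(parts, collapse = strrep("N", sample(c(5, 26, 80), 1)))
    expect_setequal(canonical_kmers(condense_n_runs(s), 11)$code,
                    canonical_kmers(s, 11)$code)
  }
})

test_that("index values reflect exclusive and shared k-mer origin", {
  # identical references: every k-mer is 'both'
  gp <- make_genome_pair(500, divergence = 0, seed = 2)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 3)
  cc <- index_category_counts(idx)
  expect_equal(unname(cc[c("host", "graft", "weak_host", "weak_graft")]),
               rep(0, 4))
  expect_gt(cc[["both"]], 0)
  # disjoint k-mer sets: values 1 and 2 only
  idx2 <- build_index_from_sequences("ACGTACGTA", "TTTTTTTTT", k = 5, seed = 4)
  e <- cuckoo_entries(idx2$store)
  expect_setequal(e$value, c(1, 2))
  expect_setequal(e$key[e$value == 1], canonical_kmers("ACGTACGTA", 5)$code)
  expect_setequal(e$key[e$value == 2], canonical_kmers("TTTTTTTTT", 5)$code)
})

test_that("category counts equal a set-based recomputation on synthetic genomes", {
  gp <- make_genome_pair(10000, divergence = 0.03, shared_fraction = 0.2, seed = 5)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 6)
  oracle <- oracle_category_values(gp$host, gp$graft, 25)
  e <- cuckoo_entries(idx$store)
  expect_equal(nrow(e), length(oracle))
  expect_equal(e$value[order(e$key)],
               unname(oracle[order(as.numeric(names(oracle)))]))
})

test_that("weak marking finds exactly the cross-species distance-1 pairs", {
  # middle-base worked case: single host and graft 7-mers differing centrally
  idx <- build_index_from_sequences("AAAAAAA", "AAATAAA", k = 7, seed = 7)
  mark_weak(idx, chunks = 1)
  e <- cuckoo_entries(idx$store)
  expect_setequal(e$value, c(5, 6))     # both marked weak
  # identical genomes: nothing to mark
  gp0 <- make_genome_pair(400, divergence = 0, seed = 8)
  idx0 <- build_index_from_sequences(gp0$host, gp0$graft, k = 25, seed = 9)
  mark_weak(idx0)
  expect_true(all(cuckoo_entries(idx0$store)$value == 3))
  # single-species index: no weak marks
  idx1 <- build_index_from_sequences(
    make_genome_pair(400, seed = 10)$host, "TTTTTTTTTTTTTTTTTTTTTTTTTTTT",
    k = 25, seed = 11)
  mark_weak_bruteforce(idx1)
  expect_true(all(cuckoo_entries(idx1$store)$value %in% c(1, 2)))
})

test_that("chunked annotation equals the 3k-neighbor brute force and the R oracle", {
  for (i in 1:6) {
    gp <- make_genome_pair(1500, divergence = 0.01, seed = 100 + i)
    idx_a <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 200 + i)
    idx_b <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 200 + i)
    mark_weak(idx_a, chunks = 16)
    mark_weak_bruteforce(idx_b)
    ea <- cuckoo_entries(idx_a$store)
    eb <- cuckoo_entries(idx_b$store)
    expect_equal(ea$value[order(ea$key)], eb$value[order(eb$key)])
  }
  # independent all-R neighbor oracle on one small instance
  gp <- make_genome_pair(600, divergence = 0.02, seed = 300)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 13, seed = 301)
  vals_before <- with(cuckoo_entries(idx$store), setNames(value, sprintf("%.0f", key)))
  expected_weak <- oracle_weak_set(vals_before, 13)
  mark_weak(idx, chunks = 4)
  e <- cuckoo_entries(idx$store)
  expect_equal(sort(e$key[e$value > 4]), expected_weak)
})

test_that("chunk count does not change the annotation", {
  gp <- make_genome_pair(1200, divergence = 0.02, seed = 12)
  res <- lapply(c(1, 4, 16), function(ch) {
    idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 13)
    mark_weak(idx, chunks = ch)
    e <- cuckoo_entries(idx$store)
    e[order(e$key), c("key", "value")]
  })
  expect_equal(res[[1]], res[[2]])
  expect_equal(res[[2]], res[[3]])
  # idempotence: marking again changes nothing
  idx <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 13)
  mark_weak(idx); e1 <- cuckoo_entries(idx$store)
  mark_weak(idx); e2 <- cuckoo_entries(idx$store)
  expect_equal(e1, e2)
})

test_that("swapping host and graft roles swaps values 1<->2 and 5<->6 only", {
  gp <- make_genome_pair(1500, divergence = 0.02, seed = 14)
  idx_hg <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 15)
  idx_gh <- build_index_from_sequences(gp$graft, gp$host, k = 25, seed = 15)
  mark_weak(idx_hg); mark_weak(idx_gh)
  a <- cuckoo_entries(idx_hg$store); a <- a[order(a$key), ]
  b <- cuckoo_entries(idx_gh$store); b <- b[order(b$key), ]
  swap <- c(`1` = 2, `2` = 1, `3` = 3, `5` = 6, `6` = 5)
  expect_equal(a$key, b$key)
  expect_equal(unname(swap[as.character(a$value)]), b$value)
  # 'both' k-mers never carry the weak bit (value 7 must not occur)
  expect_false(any(c(a$value, b$value) == 7))
})

test_that("file-based build reads FASTA (plain and gzipped) identically", {
  gp <- make_genome_pair(800, divergence = 0.05, seed = 16)
  d <- tempfile(); dir.create(d)
  fh <- file.path(d, "host.fa"); fg <- file.path(d, "graft.fa.gz")
  write_fasta(c(host1 = gp$host), fh)
  write_fasta(c(graft1 = gp$graft), fg)
  idx <- build_index(fh, fg, k = 25, seed = 17)
  idx_mem <- build_index_from_sequences(gp$host, gp$graft, k = 25, seed = 17)
  ea <- cuckoo_entries(idx$store); eb <- cuckoo_entries(idx_mem$store)
  expect_equal(ea[order(ea$key), ], eb[order(eb$key), ])
  expect_error(build_index(file.path(d, "absent.fa"), fg, k = 25), "not found")
  expect_error(build_index_from_sequences(gp$host, gp$graft, k = 24), "odd")
})
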