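test_that("rule tree reproduces the reference decisions", {
  expect_equal(as.character(classify_stats(c(10, 0, 0, 0, 0, 0, 10))), "host")
  expect_equal(as.character(classify_stats(c(0, 0, 10, 0, 0, 0, 10))), "graft")
  expect_equal(as.character(classify_stats(c(0, 0, 0, 0, 8, 0, 8))), "both")
  expect_equal(as.character(classify_stats(c(0, 0, 0, 0, 0, 8, 8))), "neither")
  expect_equal(as.character(classify_stats(c(1, 0, 1, 0, 0, 6, 8))), "neither")
  expect_equal(as.character(classify_stats(c(0, 1, 0, 1, 0, 0, 2))), "ambiguous")
  expect_equal(as.character(classify_stats(c(0, 0, 0, 0, 0, 0, 0))), "neither")
  # rule 2: no strong graft, few weak graft, some strong host
  expect_equal(as.character(classify_stats(c(8, 0, 0, 3, 10, 9, 30))), "host")
  # symmetric near-tie resolves to ambiguous, not an order artifact
  expect_equal(as.character(classify_stats(c(2, 0, 2, 0, 0, 4, 8))), "ambiguous")
  expect_error(classify_stats(c(1, 0, 0, 0, 0, 0, 5)), "sum")
  expect_error(classify_stats(c(-1, 1, 0, 0, 0, 0, 0)), "negative")
})

test_that("classification is total, deterministic and host/graft symmetric", {
  set.seed(17)
  n_cases <- 20000
  m <- matrix(rpois(6 * n_cases, lambda = sample(c(0.3, 2, 10), 6 * n_cases, TRUE)),
              ncol = 6)
  # sprinkle structural zeros so the quick branches are exercised
  m[sample(length(m), length(m) / 3)] <- 0
  stats <- cbind(m, rowSums(m))
  lab <- classify_stats(stats)
  expect_false(any(is.na(lab)))                       # totality
  expect_equal(classify_stats(stats), lab)            # determinism
  swapped <- stats[, c(3, 4, 1, 2, 5, 6, 7)]
  lab_sw <- classify_stats(swapped)
  map <- c(host = "graft", graft = "host", both = "both",
           neither = "neither", ambiguous = "ambiguous")
  expect_equal(as.character(lab_sw), unname(map[as.character(lab)]))
})

test_that("fragment statistics match an R-level recount", {
  fx <- make_fixture_index(len = 3000, divergence = 0.05, k = 25, seed = 71)
  mark_weak(fx$idx)
  rs <- make_read_set(list(host = fx$gp$host, graft = fx$gp$graft), 150,
                      read_len = 120, error_rate = 0.01, seed = 72)
  st <- fragment_stats(fx$idx, rs$reads1)
  expect_true(all(rowSums(st[, 1:6]) == st$n))
  recount <- t(vapply(rs$reads1, function(r) {
    v <- cuckoo_lookup(fx$idx$store, canonical_kmers(r, 25)$code)
    c(h = sum(v == 1, na.rm = TRUE), hw = sum(v == 5, na.rm = TRUE),
      g = sum(v == 2, na.rm = TRUE), gw = sum(v == 6, na.rm = TRUE),
      b = sum(v == 3, na.rm = TRUE), x = sum(is.na(v)), n = length(v))
  }, numeric(7), USE.NAMES = FALSE))
  expect_equal(as.matrix(st), recount, ignore_attr = TRUE)
  # paired stats are the mate sums
  rsp <- make_read_set(list(host = fx$gp$host), 40, read_len = 100,
                       paired = TRUE, insert_size = 250, error_rate = 0, seed = 73)
  stp <- fragment_stats(fx$idx, rsp$reads1, rsp$reads2)
  st1 <- fragment_stats(fx$idx, rsp$reads1)
  st2 <- fragment_stats(fx$idx, rsp$reads2)
  expect_equal(stp, st1 + st2)
})

test_that("N windows are excluded from fragment counts", {
  fx <- make_fixture_index(len = 2000, k = 25, seed = 74)
  read <- substr(fx$gp$host, 101, 250)
  stats0 <- fragment_stats(fx$idx, read)
  withN <- paste0(substr(read, 1, 74), "N", substr(read, 76, 150))
  stats1 <- fragment_stats(fx$idx, withN)
  expect_equal(stats1$n, stats0$n - 25)  # windows covering the N vanish
})

test_that("quick mode agrees with full classification when evidence is uniform", {
  fx <- make_fixture_index(len = 4000, divergence = 0.15, k = 25, seed = 75)
  mark_weak(fx$idx)
  rs <- make_read_set(list(host = fx$gp$host, graft = fx$gp$graft), 400,
                      read_len = 120, error_rate = 0, seed = 76)
  full <- classify_fragments(fx$idx, rs$reads1)
  quick <- classify_fragments(fx$idx, rs$reads1, quick = TRUE)
  # error-free reads from divergent genomes: sampled k-mers agree with the bulk
  expect_gt(mean(quick == full), 0.98)
  # too-short reads always fall back to the full path
  shorts <- substr(rs$reads1[1:20], 1, 26)   # two valid k-mers only
  expect_equal(classify_fragments(fx$idx, shorts, quick = TRUE),
               classify_fragments(fx$idx, shorts))
  # paired quick mode with four agreeing graft samples
  rsp <- make_read_set(list(graft = fx$gp$graft), 50, read_len = 100,
                       paired = TRUE, insert_size = 220, error_rate = 0, seed = 77)
  qp <- classify_fragments(fx$idx, rsp$reads1, rsp$reads2, quick = TRUE)
  fp <- classify_fragments(fx$idx, rsp$reads1, rsp$reads2)
  expect_true(all(as.character(qp) %in% c("graft", "both")))
  expect_gt(mean(qp == fp), 0.95)
})

test_that("error-free host fragments never classify as graft", {
  fx <- make_fixture_index(len = 5000, divergence = 0.2, k = 25, seed = 78)
  mark_weak(fx$idx)
  rs <- make_reads(fx$gp$host, 300, read_len = 150, error_rate = 0, seed = 79)
  lab <- classify_fragments(fx$idx, rs$reads1)
  expect_true(all(as.character(lab) %in% c("host", "both")))
})
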