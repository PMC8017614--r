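# Independent oracles used across the suite.  These deliberately avoid the
# package's own fast paths: string manipulation instead of bit tricks, a
# plain R environment instead of the Cuckoo store.

# string-level reverse complement (independent of revcomp_code)
str_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# base-4 encoding by positional arithmetic on characters
str_encode <- function(s) {
  d <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  sum(d * 4^(rev(seq_along(d)) - 1))
}

# associative-array oracle for the key-value store
env_store <- function() new.env(hash = TRUE, parent = emptyenv())
env_insert <- function(env, keys, values) {
  values <- rep_len(values, length(keys))
  for (i in seq_along(keys)) {
    kk <- sprintf("%.0f", keys[i])
    old <- env[[kk]]
    env[[kk]] <- if (is.null(old)) values[i] else if (old == values[i]) old else 3L
  }
  env
}
env_lookup <- function(env, keys) {
  vapply(keys, function(k) {
    v <- env[[sprintf("%.0f", k)]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
}

# all valid canonical k-mer codes of a set of sequences, via the exported
# per-sequence iterator (used as the set oracle for index construction)
seq_canonical_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) canonical_kmers(s, k)$code)))
}

# category counts of an index recomputed from first principles on sequences
oracle_category_values <- function(host_seqs, graft_seqs, k) {
  hs <- seq_canonical_set(host_seqs, k)
  gs <- seq_canonical_set(graft_seqs, k)
  keys <- union(hs, gs)
  val <- integer(length(keys))
  val[keys %in% hs & !(keys %in% gs)] <- 1L
  val[!(keys %in% hs) & keys %in% gs] <- 2L
  val[keys %in% hs & keys %in% gs] <- 3L
  names(val) <- sprintf("%.0f", keys)
  val
}

# weak set recomputed by querying all 3k Hamming-1 neighbors per exclusive
# k-mer, entirely in R (independent of both C++ annotation paths)
oracle_weak_set <- function(values, k) {
  keys <- as.numeric(names(values))
  present <- values
  is_weak <- logical(length(keys))
  for (i in seq_along(keys)) {
    v <- values[i]
    if (v != 1 && v != 2) next
    s <- decode_kmer(keys[i], k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    found <- FALSE
    for (pos in seq_len(k)) {
      for (alt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        nb <- ch; nb[pos] <- alt
        nc <- canonical_code(str_encode(paste(nb, collapse = "")), k)
        nv <- present[sprintf("%.0f", nc)]
        if (!is.na(nv) && ((v == 1 && nv %in% c(2, 3)) ||
                           (v == 2 && nv %in% c(1, 3)))) {
          found <- TRUE; break
        }
      }
      if (found) break
    }
    is_weak[i] <- found
  }
  sort(keys[is_weak])
}

# small fixture: indexed synthetic genome pair
make_fixture_index <- function(len = 3000, divergence = 0.05, k = 25,
                               seed = 42, ...) {
  gp <- make_genome_pair(len, divergence = divergence, seed = seed)
  idx <- build_index_from_sequences(gp$host, gp$graft, k = k, seed = seed + 1, ...)
  list(gp = gp, idx = idx)
}
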