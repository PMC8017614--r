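#' Create a bucketed Cuckoo k-mer store
#'
#' Allocates an empty (3,4)-bucketed Cuckoo hash table with quotienting
#' for canonical k-mer keys.  The bucket count is
#' `p = ceiling(expected_keys / (4 * target_load))`; three random affine
#' hash functions are drawn from `seed`.  Each slot is bit-packed as a
#' 2-bit hash-choice tag (0 = empty), a 3-bit species value and a
#' `quotient_bits(k, p)`-bit quotient; two shortcut flag bits are kept
#' per bucket.
#'
#' Species values are 1 (host), 2 (graft), 3 (both), 5 (weak host),
#' 6 (weak graft).  Deletion is not supported by contract: the random-walk
#' insertion keeps a tight layout (no stored key could be moved to an
#' earlier-choice bucket with a free slot), which lets unsuccessful
#' lookups stop at the first bucket with an empty slot, and keeps the
#' monotone shortcut bits valid.
#'
#' @param expected_keys expected number of distinct keys (>= 1); the
#'   total reference length is a good over-estimate.
#' @param target_load design load factor in (0, 0.999].
#' @param k k-mer length (1..31; odd k required for index use).
#' @param seed integer seed for hash parameters and the insertion walk.
#' @param shortcut_mode 0, 1 or 2 extra per-bucket flag bits consulted to
#'   stop unsuccessful lookups early; never changes lookup results.
#' @param prefetch_level advisory memory-prefetch level 0/1/2; accepted
#'   for interface compatibility, results are invariant.
#' @param max_walk maximum eviction-walk length of a single insertion
#'   walk (default 5000).
#' @param walk_retries number of times a too-long walk is rolled back
#'   (the table is restored exactly) and retried with fresh randomness
#'   before the insertion is declared failed (default 20).  Retries are
#'   the per-insertion analogue of restarting construction with a
#'   different random seed; near the load limit single walks have a
#'   heavy-tailed length distribution, and a rolled-back retry is far
#'   cheaper than rebuilding.
#' @return an object of class `cuckoo_store` (external pointer).
#' @examples
#' st <- cuckoo_new(88, target_load = 0.88, k = 25, seed = 1)
#' cuckoo_params(st)$p  # 25 buckets, capacity 100
#' @export
cuckoo_new <- function(expected_keys, target_load = 0.88, k = 25, seed = 1,
                       shortcut_mode = 2, prefetch_level = 0,
                       max_walk = 5000, walk_retries = 20) {
  stopifnot(shortcut_mode %in% 0:2, prefetch_level %in% 0:2, max_walk >= 1,
            walk_retries >= 0)
  ptr <- .cpp_store_new(as.numeric(expected_keys), as.numeric(target_load),
                        as.integer(k), as.numeric(seed),
                        as.integer(shortcut_mode), as.integer(prefetch_level),
                        as.integer(max_walk), as.integer(walk_retries))
  structure(ptr, class = "cuckoo_store")
}

#' Store parameters and occupancy
#'
#' @param store a `cuckoo_store`.
#' @return list of parameters (k, h, b, p, capacity, load, hash
#'   parameters, ...).
#' @export
cuckoo_params <- function(store) {
  .cpp_store_params(store)
}

#' @export
print.cuckoo_store <- function(x, ...) {
  p <- cuckoo_params(x)
  cat(sprintf("(3,4)-bucketed Cuckoo k-mer store: k=%d, p=%s buckets, %s/%s slots used (load %.3f)\n",
              p$k, format(p$p, big.mark = ","), format(p$n_keys, big.mark = ","),
              format(p$capacity, big.mark = ","), p$load))
  invisible(x)
}

#' Insert canonical k-mer keys
#'
#' Inserts keys with species values (1 host, 2 graft, 3 both).  A key
#' already present has its value combined: inserting a host k-mer again
#' as graft updates the value to both (see [combine_values()]).  New keys
#' go to the first free slot among their three buckets in choice order;
#' if all 12 slots are full, a uniformly random one of them is evicted
#' and relocated (random walk).  After `max_walk` evictions the build is
#' declared failed and the caller should restart with a larger table or
#' a different seed.
#'
#' @param store a `cuckoo_store`.
#' @param keys numeric vector of canonical codes in `[0, 4^k)`.
#' @param values integer vector (length 1 or `length(keys)`) in 1..3.
#' @return invisibly, a list with `inserted` (count before any failure)
#'   and `failed` (logical).
#' @export
cuckoo_insert <- function(store, keys, values) {
  res <- .cpp_store_insert(store, as.numeric(keys), as.integer(values))
  if (res$failed)
    warning("insertion walk exceeded max_walk: table too full; restart with a larger table or different seed")
  invisible(res)
}

#' Look up canonical k-mer keys
#'
#' Probes the key's buckets in choice order 1, 2, 3.  A slot matches iff
#' its choice tag equals the probe index and its quotient equals the
#' key's quotient.  Probing stops early at a bucket with an empty slot
#' (tight layout) or when shortcut bits prove no later bucket can hold
#' the key; early stopping never changes the result.
#'
#' @param store a `cuckoo_store`.
#' @param keys numeric vector of canonical codes.
#' @return integer vector of species values; `NA` where absent.
#' @export
cuckoo_lookup <- function(store, keys) {
  .cpp_store_lookup(store, as.numeric(keys))
}

#' Buckets probed per lookup
#'
#' Instrumented lookup returning how many buckets were examined for each
#' key (1..3); useful for verifying that shortcut bits only reduce work.
#'
#' @inheritParams cuckoo_lookup
#' @return integer vector of probe counts.
#' @export
cuckoo_probe_counts <- function(store, keys) {
  .cpp_store_probe_counts(store, as.numeric(keys))
}

#' Switch shortcut / prefetch mode of an existing store
#'
#' Only affects how lookups terminate early; results are invariant.
#'
#' @param store a `cuckoo_store`.
#' @param shortcut_mode 0, 1 or 2.
#' @param prefetch_level 0, 1 or 2 (advisory).
#' @return the store, invisibly.
#' @export
cuckoo_set_mode <- function(store, shortcut_mode = NULL, prefetch_level = NULL) {
  p <- cuckoo_params(store)
  sm <- if (is.null(shortcut_mode)) p$shortcut_mode else shortcut_mode
  pl <- if (is.null(prefetch_level)) p$prefetch_level else prefetch_level
  stopifnot(sm %in% 0:2, pl %in% 0:2)
  .cpp_store_set_mode(store, as.integer(sm), as.integer(pl))
  invisible(store)
}

#' Combine species values on repeated insertion
#'
#' host + host = host; graft + graft = graft; host + graft (either
#' order) = both; both absorbs everything.  Weak-flagged values are not
#' allowed during build (the weak bit is set only by [mark_weak()]).
#'
#' @param old,new integer values in 1..3.
#' @return combined integer value.
#' @export
combine_values <- function(old, new) {
  stopifnot(all(old %in% 1:3), all(new %in% 1:3))
  ifelse(old == new, old, 3L)
}

#' Set the weak bit on a stored exclusive k-mer
#'
#' Marks a stored host (1) or graft (2) k-mer as weak (5 or 6).
#' Idempotent.  Keys that are absent or have value both (3) violate the
#' contract and raise an error.
#'
#' @inheritParams cuckoo_lookup
#' @return the store, invisibly.
#' @export
cuckoo_set_weak <- function(store, keys) {
  .cpp_store_set_weak(store, as.numeric(keys))
  invisible(store)
}

#' Fill statistics of a store
#'
#' Scans the table and reports the load factor, the fraction of stored
#' keys resting at each hash choice, and the implied mean number of
#' bucket probes for a present key, `sum_i i * fraction_i`.
#'
#' @param store a non-empty `cuckoo_store`.
#' @return list with `load`, `choice_fractions` (length 3),
#'   `mean_probes_present`, `value_counts` (index = value) and `n_keys`.
#' @export
cuckoo_fill_stats <- function(store) {
  .cpp_store_fill_stats(store)
}

#' All stored entries
#'
#' Reconstructs every stored key from its bucket, quotient and choice
#' tag; mainly for testing and diagnostics.
#'
#' @param store a `cuckoo_store`.
#' @return data.frame with columns `key`, `value`, `choice`, `bucket`.
#' @export
cuckoo_entries <- function(store) {
  as.data.frame(.cpp_store_entries(store))
}

#' Per-bucket occupancy and shortcut bits
#'
#' @param store a `cuckoo_store`.
#' @return data.frame with columns `occupied` (0..4) and `shortcut_bits`.
#' @keywords internal
#' @export
cuckoo_bucket_fill <- function(store) {
  as.data.frame(.cpp_store_bucket_fill(store))
}

#' Save / load a store
#'
#' Writes the store to a little-endian binary file: an 8-byte magic
#' string `"XSORTIX1"`, a format version, the parameters (k, h, b, p,
#' target load, seed, shortcut mode, prefetch level, walk limit, the
#' three (a, b) hash-parameter pairs, key count, quotient width) and the
#' packed slot and shortcut-bit arrays.  The round trip is exact: a
#' reloaded store answers all lookups identically.
#'
#' @param store a `cuckoo_store`.
#' @param path file path.
#' @return `cuckoo_save`: the path, invisibly.  `cuckoo_load`: the store.
#' @export
cuckoo_save <- function(store, path) {
  .cpp_store_save(store, path.expand(path))
  invisible(path)
}

#' @rdname cuckoo_save
#' @export
cuckoo_load <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  structure(.cpp_store_load(path.expand(path)), class = "cuckoo_store")
}

#' Count bucket configurations
#'
#' With slots inside a bucket kept in a canonical order, a bucket's
#' configuration is described by the non-negative (h+1)-tuple
#' (c_h, ..., c_1, c_0) summing to b, where c_i counts slots holding an
#' i-th-choice key and c_0 the empty slots.  Counting these tuples (by
#' enumeration) bounds the bits needed for a compressed configuration
#' encoding; for (h, b) = (3, 4) there are 35, fitting in 6 bits.
#'
#' @param h number of hash functions.
#' @param b slots per bucket.
#' @return integer count of configurations.
#' @examples
#' count_bucket_configurations(3, 4)  # 35
#' @export
count_bucket_configurations <- function(h, b) {
  stopifnot(h >= 1, b >= 1)
  # enumerate (h+1)-tuples of non-negative integers summing to b
  grids <- rep(list(0:b), h + 1)
  tuples <- do.call(expand.grid, grids)
  sum(rowSums(tuples) == b)
}

#' Count joint value combinations of a bucket
#'
#' `num_values ^ b` possible joint value assignments for the b slots of
#' a bucket; e.g. 5 species values in 4 slots give 625 combinations,
#' encodable in 10 bits instead of 4 x 3 = 12.
#'
#' @param num_values size of the value set.
#' @param b slots per bucket.
#' @return numeric count.
#' @examples
#' count_value_combinations(5, 4)  # 625
#' @export
count_value_combinations <- function(num_values, b) {
  stopifnot(num_values >= 1, b >= 1)
  num_values^b
}
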