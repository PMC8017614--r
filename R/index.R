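#' Condense runs of Ns in reference sequences
#'
#' Replaces every maximal run of more than `max_run` Ns by exactly
#' `max_run` Ns.  Since k-mers containing even a single N are ignored,
#' this does not change the k-mer content of the reference, but it
#' shrinks assemblies whose alternative-allele scaffolds are mostly
#' padding Ns.
#'
#' @param seq character vector of sequences (may contain ambiguity
#'   codes).
#' @param max_run maximum N-run length to keep (default 25).
#' @return character vector with long N runs condensed.
#' @examples
#' condense_n_runs(paste0("A", strrep("N", 100), "C"))  # "A" + 25 Ns + "C"
#' @export
condense_n_runs <- function(seq, max_run = 25) {
  stopifnot(max_run >= 1)
  gsub(sprintf("[Nn]{%d,}", max_run + 1), strrep("N", max_run), seq, perl = TRUE)
}

#' Build a k-mer index from host and graft references
#'
#' Reads the host and graft FASTA files (plain or gzipped), condenses
#' long N runs, and inserts every valid canonical k-mer into a Cuckoo
#' store with species value host (1) or graft (2); k-mers seen in both
#' references get value both (3).  The expected key count is estimated
#' by the total reference length (an over-estimate, since duplicate
#' k-mers collapse).  If the insertion walk fails, the build is retried
#' with the next seed, up to `retries` times.
#'
#' Weak k-mers are not annotated here; call [mark_weak()] afterwards
#' (or use [run_index()] which does both).
#'
#' @param host_refs,graft_refs character vectors of FASTA file paths.
#' @param k odd k-mer length in 1..31 (default 25).
#' @param target_load design load factor (default 0.88).
#' @param seed build seed (hash parameters + insertion walk).
#' @param shortcut_mode,prefetch_level,max_walk see [cuckoo_new()].
#' @param retries extra build attempts with incremented seed.
#' @return an object of class `xenosort_index`.
#' @export
build_index <- function(host_refs, graft_refs, k = 25, target_load = 0.88,
                        seed = 1, shortcut_mode = 2, prefetch_level = 0,
                        max_walk = 5000, retries = 3) {
  host_seqs <- read_fasta_sequences(host_refs)
  graft_seqs <- read_fasta_sequences(graft_refs)
  idx <- build_index_from_sequences(host_seqs, graft_seqs, k = k,
                                    target_load = target_load, seed = seed,
                                    shortcut_mode = shortcut_mode,
                                    prefetch_level = prefetch_level,
                                    max_walk = max_walk, retries = retries)
  idx$meta$host_files <- normalizePath(host_refs)
  idx$meta$graft_files <- normalizePath(graft_refs)
  dig <- tryCatch(tools::md5sum(c(host_refs, graft_refs)), error = function(e) NULL)
  idx$meta$source_md5 <- unname(dig)
  idx
}

#' @describeIn build_index Build from in-memory character sequences
#'   instead of FASTA files (used by tests and the synthetic-data
#'   generator).
#' @param host_seqs,graft_seqs character vectors of sequences.
#' @export
build_index_from_sequences <- function(host_seqs, graft_seqs, k = 25,
                                       target_load = 0.88, seed = 1,
                                       shortcut_mode = 2, prefetch_level = 0,
                                       max_walk = 5000, retries = 3) {
  stopifnot(k >= 1, k <= 31)
  if (k %% 2 == 0) stop("index construction requires odd k (weak-k-mer annotation needs a middle base)")
  host_seqs <- condense_n_runs(host_seqs)
  graft_seqs <- condense_n_runs(graft_seqs)
  expected <- sum(nchar(host_seqs)) + sum(nchar(graft_seqs))
  if (expected < 1) stop("empty reference sequences")
  for (attempt in 0:retries) {
    store <- cuckoo_new(expected, target_load = target_load, k = k,
                        seed = seed + attempt, shortcut_mode = shortcut_mode,
                        prefetch_level = prefetch_level, max_walk = max_walk)
    ok <- .cpp_store_insert_sequences(store, host_seqs, 1L) &&
      .cpp_store_insert_sequences(store, graft_seqs, 2L)
    if (ok) {
      idx <- structure(list(store = store, k = k,
                            meta = list(seed = seed + attempt,
                                        target_load = target_load,
                                        weak_marked = FALSE)),
                       class = "xenosort_index")
      return(idx)
    }
  }
  stop("index construction failed after ", retries + 1,
       " attempts (insertion walk exceeded); increase the table size or change the seed")
}

#' Annotate weak k-mers
#'
#' Marks every host- or graft-exclusive k-mer that has a
#' Hamming-distance-1 neighbor attributed to the other species (including
#' both-species k-mers) by setting the weak bit on its value (1 -> 5,
#' 2 -> 6).  Works by extracting the complete list of stored k-mers and
#' their reverse complements in `chunks` partitions by leading bases,
#' sorting each chunk, and scanning:
#' a distance-1 pair differs in its l-suffix (found within blocks of
#' constant (l+1)-prefix), in the l-suffix of its reverse complement
#' (covered because both orientations are listed), or in its middle base
#' (found after re-sorting blocks of constant l-prefix with the order of
#' middle base and l-suffix swapped), where k = 2l + 1.  Idempotent.
#'
#' @param index a `xenosort_index`.
#' @param chunks 1, 4 or 16 partitions by the first 0/1/2 bases; the
#'   result does not depend on it.
#' @return the index, invisibly (values updated in place).
#' @export
mark_weak <- function(index, chunks = 16) {
  stopifnot(inherits(index, "xenosort_index"))
  n <- .cpp_mark_weak_chunked(index$store, as.integer(chunks))
  index$meta$weak_marked <- TRUE
  index$meta$weak_marks <- n
  invisible(index)
}

#' @describeIn mark_weak Reference annotation by direct enumeration of
#'   all 3k Hamming-distance-1 neighbors of every stored exclusive
#'   k-mer; quadratically slower but independent of the sort-and-scan
#'   algorithm, so it serves as its cross-check.
#' @export
mark_weak_bruteforce <- function(index) {
  stopifnot(inherits(index, "xenosort_index"))
  n <- .cpp_mark_weak_bruteforce(index$store)
  index$meta$weak_marked <- TRUE
  index$meta$weak_marks <- n
  invisible(index)
}

#' Index category counts
#'
#' Counts stored k-mers per species value, Table-style: host, graft,
#' both, weak host, weak graft.
#'
#' @param index a `xenosort_index`.
#' @return named numeric vector.
#' @export
index_category_counts <- function(index) {
  vc <- cuckoo_fill_stats(index$store)$value_counts
  c(host = vc[2], graft = vc[3], both = vc[4],
    weak_host = vc[6], weak_graft = vc[7])
}

#' Save / load a k-mer index
#'
#' The index file is the binary store format of [cuckoo_save()]; build
#' metadata is stored alongside in a JSON sidecar `<path>.json`.
#'
#' @param index a `xenosort_index`.
#' @param path index file path.
#' @return `save_index`: the path, invisibly; `load_index`: the index.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "xenosort_index"))
  cuckoo_save(index$store, path)
  meta <- index$meta
  meta$k <- index$k
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  store <- cuckoo_load(path)
  k <- cuckoo_params(store)$k
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(weak_marked = NA)
  }
  structure(list(store = store, k = k, meta = meta), class = "xenosort_index")
}

#' @export
print.xenosort_index <- function(x, ...) {
  p <- cuckoo_params(x$store)
  cat(sprintf("xenosort k-mer index: k=%d, %s k-mers, load %.3f, weak-marked: %s\n",
              x$k, format(p$n_keys, big.mark = ","), p$load,
              as.character(isTRUE(x$meta$weak_marked))))
  if (p$n_keys > 0) {
    cc <- index_category_counts(x)
    cat("  ", paste(names(cc), cc, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

# internal: read (possibly gzipped) FASTA into a plain character vector
read_fasta_sequences <- function(paths) {
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("reference file not found: ", paste(miss, collapse = ", "))
  unlist(lapply(paths, function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = "fasta"))
  }), use.names = FALSE)
}
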