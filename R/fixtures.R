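# Synthetic host/graft genomes and labeled read sets.  Substitution-only
# divergence and sequencing errors (no indels): the weak-k-mer model is
# Hamming-centric, and these generators emulate exactly that regime.

#' Generate a synthetic host/graft genome pair
#'
#' Draws a random host sequence and derives the graft from it by
#' independent per-base substitutions at rate `divergence`, leaving an
#' optional contiguous central block (`shared_fraction` of the length)
#' identical.  Optionally injects a run of Ns into both sequences (for
#' exercising [condense_n_runs()] and N-window skipping).  Deterministic
#' given `seed`; R's global RNG state is preserved.
#'
#' @param length genome length in bp.
#' @param divergence per-base substitution probability outside the
#'   shared block (0..1).
#' @param shared_fraction fraction of the genome kept identical (a
#'   central contiguous block; default 0).
#' @param seed integer seed.
#' @param n_run optional length of an N run inserted at a random
#'   position in both sequences.
#' @return list with `host`, `graft` (character strings) and
#'   `shared_range` (0-based start/end of the identical block, or NULL).
#' @export
make_genome_pair <- function(length, divergence = 0.05, shared_fraction = 0,
                             seed = 1, n_run = NULL) {
  stopifnot(length >= 1, divergence >= 0, divergence <= 1,
            shared_fraction >= 0, shared_fraction <= 1)
  with_preserved_seed(seed, {
    bases <- c("A", "C", "G", "T")
    host <- sample(bases, length, replace = TRUE)
    graft <- host
    shared <- NULL
    mutable <- rep(TRUE, length)
    if (shared_fraction > 0) {
      w <- floor(shared_fraction * length)
      s <- floor((length - w) / 2)
      if (w > 0) {
        mutable[(s + 1):(s + w)] <- FALSE
        shared <- c(start = s, end = s + w)
      }
    }
    hit <- mutable & (runif(length) < divergence)
    if (any(hit)) {
      # substitute with one of the three other bases, uniformly
      shift <- sample(1:3, sum(hit), replace = TRUE)
      old <- match(graft[hit], bases) - 1L
      graft[hit] <- bases[((old + shift) %% 4L) + 1L]
    }
    if (!is.null(n_run) && n_run >= 1 && length > n_run) {
      at <- sample.int(length - n_run, 1)
      host[at:(at + n_run - 1)] <- "N"
      graft[at:(at + n_run - 1)] <- "N"
    }
    list(host = paste(host, collapse = ""),
         graft = paste(graft, collapse = ""),
         shared_range = shared)
  })
}

#' Sample labeled reads from one genome
#'
#' Uniform start positions, random strand, independent substitution
#' errors at `error_rate`.  Paired mode samples a fragment of
#' `insert_size` bp and returns the two mates in standard
#' forward/reverse-complement orientation.
#'
#' @param genome a single sequence (character string).
#' @param n_reads number of fragments.
#' @param read_len read length in bp (default 150).
#' @param error_rate per-base substitution error probability.
#' @param paired produce read pairs.
#' @param insert_size fragment length for paired mode (default 300).
#' @param seed integer seed.
#' @param id_prefix read name prefix.
#' @return list with `id`, `reads1`, `reads2` (NULL if single-end),
#'   `pos` (0-based fragment starts) and `strand`.
#' @export
make_reads <- function(genome, n_reads, read_len = 150, error_rate = 0.01,
                       paired = FALSE, insert_size = 300, seed = 1,
                       id_prefix = "read") {
  glen <- nchar(genome)
  span <- if (paired) insert_size else read_len
  stopifnot(span <= glen, n_reads >= 1, error_rate >= 0, error_rate <= 1)
  with_preserved_seed(seed, {
    pos <- sample.int(glen - span + 1, n_reads, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    frag <- substring(genome, pos + 1, pos + span)
    rc <- revcomp_string(frag)
    frag <- ifelse(strand == "+", frag, rc)
    if (paired) {
      r1 <- substring(frag, 1, read_len)
      r2 <- revcomp_string(substring(frag, span - read_len + 1, span))
      r1 <- add_substitution_errors(r1, error_rate)
      r2 <- add_substitution_errors(r2, error_rate)
    } else {
      r1 <- add_substitution_errors(frag, error_rate)
      r2 <- NULL
    }
    list(id = sprintf("%s%06d", id_prefix, seq_len(n_reads)),
         reads1 = r1, reads2 = r2, pos = pos, strand = strand)
  })
}

#' Generate a labeled mixed read set
#'
#' Draws reads from several source genomes (typically host, graft and an
#' unrelated "neither" genome), shuffles them, and records the true
#' origin of every fragment.  Used for end-to-end validation of the
#' classifier.
#'
#' @param genomes named list of sequences, e.g.
#'   `list(host = ..., graft = ...)`; names become the truth labels.
#' @param n_reads reads per source (single number or per-source vector).
#' @inheritParams make_reads
#' @return list with `id`, `reads1`, `reads2`, `label` (true origin,
#'   character) and `error_rate`.
#' @export
make_read_set <- function(genomes, n_reads, read_len = 150, error_rate = 0.01,
                          paired = FALSE, insert_size = 300, seed = 1) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  n_reads <- rep_len(n_reads, length(genomes))
  parts <- lapply(seq_along(genomes), function(i) {
    r <- make_reads(genomes[[i]], n_reads[i], read_len = read_len,
                    error_rate = error_rate, paired = paired,
                    insert_size = insert_size, seed = seed + i,
                    id_prefix = paste0(names(genomes)[i], "_"))
    r$label <- rep(names(genomes)[i], n_reads[i])
    r
  })
  out <- list(id = unlist(lapply(parts, `[[`, "id")),
              reads1 = unlist(lapply(parts, `[[`, "reads1")),
              reads2 = if (paired) unlist(lapply(parts, `[[`, "reads2")) else NULL,
              label = unlist(lapply(parts, `[[`, "label")),
              error_rate = error_rate)
  with_preserved_seed(seed, {
    ord <- sample.int(length(out$id))
    out$id <- out$id[ord]
    out$reads1 <- out$reads1[ord]
    if (paired) out$reads2 <- out$reads2[ord]
    out$label <- out$label[ord]
  })
  out
}

#' Write a labeled read set to FASTQ (+ truth TSV)
#'
#' @param rs a read set from [make_read_set()] or [make_reads()].
#' @param prefix output path prefix; writes `<prefix>.1.fq` (and `.2.fq`
#'   when paired, else `<prefix>.fq`) plus `<prefix>.truth.tsv` when
#'   labels are present.
#' @return character vector of written files, invisibly.
#' @export
write_read_set <- function(rs, prefix) {
  qual1 <- strrep("I", nchar(rs$reads1))
  files <- character(0)
  if (!is.null(rs$reads2)) {
    f1 <- paste0(prefix, ".1.fq"); f2 <- paste0(prefix, ".2.fq")
    write_fastq(rs$id, rs$reads1, qual1, f1)
    write_fastq(rs$id, rs$reads2, strrep("I", nchar(rs$reads2)), f2)
    files <- c(f1, f2)
  } else {
    f1 <- paste0(prefix, ".fq")
    write_fastq(rs$id, rs$reads1, qual1, f1)
    files <- f1
  }
  if (!is.null(rs$label)) {
    ft <- paste0(prefix, ".truth.tsv")
    write.table(data.frame(id = rs$id, label = rs$label), ft,
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, ft)
  }
  invisible(files)
}

# internal: vectorized reverse complement of plain character sequences
revcomp_string <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTacgtUu", "TGCAtgcaAa", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# internal: per-base substitution errors at a fixed rate
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < rate & v %in% bases)
    if (length(hit)) {
      shift <- sample(1:3, length(hit), replace = TRUE)
      old <- match(v[hit], bases) - 1L
      v[hit] <- bases[((old + shift) %% 4L) + 1L]
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Random distinct canonical k-mer keys
#'
#' Draws `n` distinct canonical codes uniformly (via rejection from the
#' full code space).  Each raw code combines two RNG draws so that all
#' 2k bits are random (a single `runif` draw has only 32-bit
#' granularity, which would place keys on a coarse lattice and distort
#' hash-table experiments).
#'
#' @param n number of distinct keys.
#' @param k k-mer length (13..26 for this interface).
#' @param seed integer seed.
#' @return numeric vector of `n` distinct canonical codes.
#' @export
random_canonical_keys <- function(n, k, seed = 1) {
  stopifnot(k >= 13, k <= 26, n >= 1, n <= 4^k / 4)
  with_preserved_seed(seed, {
    ks <- numeric(0)
    while (length(ks) < n) {
      m <- ceiling((n - length(ks)) * 2.2) + 16
      raw <- floor(runif(m, 0, 2^(2 * k - 25))) * 2^25 + floor(runif(m, 0, 2^25))
      ks <- unique(c(ks, canonical_code(raw, k)))
    }
    ks[seq_len(n)]
  })
}
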