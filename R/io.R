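#' Read a FASTQ file
#'
#' Thin wrapper over Biostrings: returns ids, sequences and qualities as
#' character vectors.  Gzipped input is handled transparently.
#'
#' @param path FASTQ file (plain or .gz).
#' @return list with `id`, `seq`, `qual` character vectors.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(x), seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a FASTQ file
#'
#' @param id,seq,qual character vectors of equal length.
#' @param path output file; a `.gz` suffix or `compress = TRUE` gzips.
#' @param compress force gzip compression.
#' @return the path, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path, compress = grepl("\\.gz$", path)) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = compress)
  invisible(path)
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file; `.gz` suffix gzips.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# internal: load paired FASTQ inputs and check synchronization
load_fragments <- function(fastq, pairs = NULL) {
  r1 <- read_fastq(fastq)
  r2 <- NULL
  if (!is.null(pairs)) {
    r2 <- read_fastq(pairs)
    if (length(r2$seq) != length(r1$seq))
      stop("paired FASTQ files are desynchronized: ", length(r1$seq),
           " vs ", length(r2$seq), " records")
    n1 <- sub("[/ ].*$", "", r1$id)
    n2 <- sub("[/ ].*$", "", r2$id)
    if (any(n1 != n2))
      stop("paired FASTQ files are desynchronized: read names differ (first mismatch: ",
           n1[which(n1 != n2)[1]], " vs ", n2[which(n1 != n2)[1]], ")")
  }
  list(r1 = r1, r2 = r2)
}

# internal: tabulate labels into the standard report
label_report <- function(labels, quick, paired) {
  counts <- table(labels)
  total <- length(labels)
  data.frame(label = class_labels(),
             count = as.integer(counts[class_labels()]),
             percent = if (total > 0) round(100 * as.integer(counts[class_labels()]) / total, 2) else 0,
             stringsAsFactors = FALSE)
}

#' Build, weak-mark and save a k-mer index
#'
#' End-to-end index construction: [build_index()] from the FASTA
#' references, [mark_weak()], then [save_index()].  The JSON sidecar
#' `<out_path>.json` records build parameters, per-category k-mer
#' counts, the realized load factor and the hash-choice distribution.
#'
#' @inheritParams build_index
#' @param out_path output index file.
#' @param chunks weak-marking chunk count (1, 4 or 16).
#' @return the `xenosort_index`, invisibly.
#' @export
run_index <- function(host_refs, graft_refs, k = 25, target_load = 0.88,
                      seed = 1, out_path, chunks = 16, shortcut_mode = 2,
                      prefetch_level = 0, max_walk = 5000, retries = 3) {
  idx <- build_index(host_refs, graft_refs, k = k, target_load = target_load,
                     seed = seed, shortcut_mode = shortcut_mode,
                     prefetch_level = prefetch_level, max_walk = max_walk,
                     retries = retries)
  idx <- mark_weak(idx, chunks = chunks)
  fs <- cuckoo_fill_stats(idx$store)
  idx$meta$category_counts <- as.list(index_category_counts(idx))
  idx$meta$total_kmers <- fs$n_keys
  idx$meta$load <- fs$load
  idx$meta$choice_fractions <- fs$choice_fractions
  idx$meta$mean_probes_present <- fs$mean_probes_present
  save_index(idx, out_path)
  message(sprintf("index: %d k-mers at load %.3f written to %s",
                  fs$n_keys, fs$load, out_path))
  invisible(idx)
}

#' Classify a FASTQ dataset and report category counts
#'
#' Classifies every fragment (read or synchronized read pair) and
#' tabulates counts and percentages per class.  No sequence output is
#' written; see [run_sort()] for the five-way split.
#'
#' @param index a `xenosort_index` or the path of a saved index.
#' @param fastq FASTQ file (R1 for paired data).
#' @param pairs optional synchronized mate file (R2).
#' @param quick quick mode (see [classify_fragments()]).
#' @param opts rule thresholds, [classify_options()].
#' @param report_path optional path for a tab-separated report
#'   (label, count, percent).
#' @return data.frame report with attributes `labels` (per-fragment
#'   factor) and `total`.
#' @export
run_count <- function(index, fastq, pairs = NULL, quick = FALSE,
                      opts = classify_options(), report_path = NULL) {
  if (is.character(index)) index <- load_index(index)
  frags <- load_fragments(fastq, pairs)
  labels <- classify_fragments(index, frags$r1$seq,
                               if (is.null(frags$r2)) NULL else frags$r2$seq,
                               quick = quick, opts = opts)
  rep <- label_report(labels, quick, !is.null(pairs))
  if (!is.null(report_path))
    write.table(rep, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("classified %d fragments (%s%s): %s",
                  length(labels), if (is.null(pairs)) "single-end" else "paired",
                  if (quick) ", quick" else "",
                  paste(rep$label, rep$count, sep = "=", collapse = " ")))
  attr(rep, "labels") <- labels
  attr(rep, "total") <- length(labels)
  rep
}

#' Classify a FASTQ dataset and sort reads into five files
#'
#' Writes one output FASTQ per class and input stream, named
#' `<out_prefix>-<class>.fq` (paired data: `-<class>.1.fq` and
#' `-<class>.2.fq`), with `.gz` appended when `compress = TRUE`.  Mates
#' always go to the same class.  Record ids, sequences and qualities are
#' passed through unchanged.
#'
#' @inheritParams run_count
#' @param out_prefix path prefix for the five output files.
#' @param compress gzip the outputs.
#' @return the report of [run_count()], with an additional attribute
#'   `files` naming the written outputs.
#' @export
run_sort <- function(index, fastq, pairs = NULL, out_prefix, quick = FALSE,
                     compress = FALSE, opts = classify_options(),
                     report_path = NULL) {
  if (is.character(index)) index <- load_index(index)
  frags <- load_fragments(fastq, pairs)
  labels <- classify_fragments(index, frags$r1$seq,
                               if (is.null(frags$r2)) NULL else frags$r2$seq,
                               quick = quick, opts = opts)
  ext <- if (compress) ".fq.gz" else ".fq"
  files <- character(0)
  for (cls in class_labels()) {
    sel <- which(labels == cls)
    if (is.null(pairs)) {
      f <- paste0(out_prefix, "-", cls, ext)
      write_fastq(frags$r1$id[sel], frags$r1$seq[sel], frags$r1$qual[sel], f)
      files <- c(files, f)
    } else {
      f1 <- paste0(out_prefix, "-", cls, ".1", ext)
      f2 <- paste0(out_prefix, "-", cls, ".2", ext)
      write_fastq(frags$r1$id[sel], frags$r1$seq[sel], frags$r1$qual[sel], f1)
      write_fastq(frags$r2$id[sel], frags$r2$seq[sel], frags$r2$qual[sel], f2)
      files <- c(files, f1, f2)
    }
  }
  rep <- label_report(labels, quick, !is.null(pairs))
  if (!is.null(report_path))
    write.table(rep, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("sorted %d fragments into %s-{%s}%s",
                  length(labels), out_prefix,
                  paste(class_labels(), collapse = ","), ext))
  attr(rep, "labels") <- labels
  attr(rep, "total") <- length(labels)
  attr(rep, "files") <- files
  rep
}
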