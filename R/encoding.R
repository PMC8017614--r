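#' Base-4 encoding of k-mers
#'
#' Encodes DNA/RNA k-mers as integers using A = 0, C = 1, G = 2, T/U = 3,
#' read left to right (the leftmost base is the most significant base-4
#' digit).  For example `"AGCG"` encodes as (0212) in base 4, i.e. 38.
#' Parsing is case-insensitive; any other character (including N) yields
#' `NA`, the invalid-k-mer sentinel.
#'
#' Codes are returned as doubles holding exact integers, which restricts
#' this interface to k <= 26 (2k <= 52 bits).  Index construction and read
#' classification handle k up to 31 internally without passing individual
#' codes through R.
#'
#' @param seq character vector of k-mers (each of length 1..26).
#' @return numeric vector of codes in `[0, 4^k)`; `NA` for invalid k-mers.
#' @examples
#' encode_kmer(c("AGCG", "CGCT"))  # 38, 103
#' @seealso [canonical_code()], [decode_kmer()]
#' @export
encode_kmer <- function(seq) {
  .cpp_encode_kmer(as.character(seq))
}

#' Decode a k-mer code back to a string
#'
#' @param code numeric vector of k-mer codes.
#' @param k k-mer length.
#' @return character vector of k-mers over ACGT.
#' @export
decode_kmer <- function(code, k) {
  stopifnot(k >= 1, k <= 26)
  .cpp_decode_kmer(as.numeric(code), as.integer(k))
}

#' Reverse-complement a k-mer code
#'
#' Computes the code of the reverse complement without going through
#' strings.  Applying it twice is the identity.
#'
#' @inheritParams decode_kmer
#' @return numeric vector of codes.
#' @examples
#' revcomp_code(38, k = 4)  # 103 (AGCG -> CGCT)
#' @export
revcomp_code <- function(code, k) {
  stopifnot(k >= 1, k <= 26)
  .cpp_revcomp_code(as.numeric(code), as.integer(k))
}

#' Canonical k-mer code
#'
#' The canonical code of a k-mer is the maximum of its own code and the
#' code of its reverse complement, so a k-mer and its reverse complement
#' share one representative.  For odd k there are exactly `4^k / 2`
#' distinct canonical codes (no k-mer is its own reverse complement).
#'
#' @inheritParams decode_kmer
#' @return numeric vector of canonical codes.
#' @examples
#' canonical_code(encode_kmer("AGCG"), k = 4)  # 103
#' canonical_code(encode_kmer("CGCT"), k = 4)  # 103
#' @export
canonical_code <- function(code, k) {
  stopifnot(k >= 1, k <= 26)
  .cpp_canonical_code(as.numeric(code), as.integer(k))
}

#' Canonical k-mers of a sequence
#'
#' Slides a window of length k over `seq` and reports the canonical code
#' of every window consisting solely of A/C/G/T/U (case-insensitive).
#' Windows containing any other character (e.g. N) are skipped, so a
#' sequence of length L without ambiguous bases yields L - k + 1 entries.
#'
#' @param seq a single DNA/RNA string.
#' @param k window length (1..26 for this R-level interface).
#' @return a data.frame with columns `pos` (0-based window start) and
#'   `code` (canonical code).
#' @examples
#' canonical_kmers("AGCG", k = 4)   # one window, code 103
#' canonical_kmers("ACNGT", k = 3)  # empty: every window covers the N
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1, k >= 1, k <= 26)
  res <- .cpp_canonical_kmers(as.character(seq), as.integer(k))
  data.frame(pos = res$pos, code = res$code)
}
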