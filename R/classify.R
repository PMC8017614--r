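#' Classification rule options
#'
#' Thresholds of the fragment classification rule tree, tuned for
#' typical high-quality short reads (100-150 bp).  All counts refer to
#' the per-fragment k-mer category vector (h, hw, g, gw, b, x; n) with
#' weighted scores `S_host = h + floor(hw/2)`,
#' `S_graft = g + floor(gw/2)` and thresholds
#' `T_host = T_graft = T_both = floor(n/4)`.
#'
#' @param min_evidence minimal weighted score for the quick host/graft
#'   call when the other species contributes no k-mers at all (default
#'   3: "at least a little evidence").
#' @param few_weak maximal opposite weak count in the no-strong-opposite
#'   rule (default 6).
#' @param some_strong minimal own strong count in the same rule
#'   (default 6).
#' @param opposite_strong_max maximal opposite strong count in the
#'   complex-evidence rule (default 2).
#' @param weak_ratio factor r in `r * opposite_weak <= S_own` of the
#'   complex-evidence rule (default 4).
#' @return a list of thresholds for [classify_stats()].
#' @export
classify_options <- function(min_evidence = 3, few_weak = 6, some_strong = 6,
                             opposite_strong_max = 2, weak_ratio = 4) {
  list(min_evidence = min_evidence, few_weak = few_weak,
       some_strong = some_strong, opposite_strong_max = opposite_strong_max,
       weak_ratio = weak_ratio)
}

#' The five fragment class labels, in canonical order
#' @export
class_labels <- function() c("host", "graft", "both", "neither", "ambiguous")

#' Classify fragments from k-mer category counts
#'
#' Applies the hierarchical rule tree to each row of the per-fragment
#' count vector (h, hw, g, gw, b, x; n): h / g count strong host / graft
#' k-mers, hw / gw weak ones, b both-species k-mers, x k-mers absent
#' from the index, and n their total.  The tree tries easy decisions
#' first:
#'
#' 1. No graft evidence at all (g + gw = 0): "host" if
#'    `S_host >= min_evidence`; else "both" if `b >= floor(n/4)`; else
#'    "neither" if `x >= 3n/4`; else "ambiguous".  Symmetrically when
#'    h + hw = 0.
#' 2. No strong graft k-mers (g = 0), few weak graft ones
#'    (`gw <= few_weak`), but some strong host evidence
#'    (`h >= some_strong`): "host"; symmetrically for "graft".
#' 3. Sufficient overall host evidence (`S_host >= floor(n/4)`), little
#'    strong graft evidence (`g <= opposite_strong_max`) and little weak
#'    graft evidence relative to host
#'    (`weak_ratio * gw <= S_host`): "host"; symmetrically for "graft".
#'    If both the host and the graft variant of this rule fire (possible
#'    only for near-symmetric vectors), the evidence is conflicting and
#'    the fragment is "ambiguous".
#' 4. `b >= floor(n/4)`: "both"; else `x >= 3n/4`: "neither"; else
#'    "ambiguous".
#'
#' Fragments without any valid k-mer (n = 0) are "neither".
#'
#' @param stats matrix or data.frame with columns h, hw, g, gw, b, x, n
#'   (as produced by [fragment_stats()]), or a single vector of length 7.
#' @param opts thresholds from [classify_options()].
#' @return factor of labels with levels [class_labels()].
#' @examples
#' classify_stats(c(10, 0, 0, 0, 0, 0, 10))      # host
#' classify_stats(c(0, 0, 0, 0, 8, 0, 8))        # both
#' @export
classify_stats <- function(stats, opts = classify_options()) {
  if (is.null(dim(stats))) stats <- matrix(stats, nrow = 1)
  stats <- as.matrix(stats)
  if (ncol(stats) != 7) stop("stats must have 7 columns: h, hw, g, gw, b, x, n")
  h <- stats[, 1]; hw <- stats[, 2]; g <- stats[, 3]; gw <- stats[, 4]
  b <- stats[, 5]; x <- stats[, 6]; n <- stats[, 7]
  if (any(stats < 0)) stop("negative k-mer counts")
  if (any(h + hw + g + gw + b + x != n)) stop("category counts do not sum to n")

  S_h <- h + hw %/% 2
  S_g <- g + gw %/% 2
  Tq <- n %/% 4

  lab <- rep(NA_character_, nrow(stats))
  todo <- function() is.na(lab)

  lab[todo() & n == 0] <- "neither"

  # quick branch: no graft k-mers at all
  mA <- todo() & (g + gw) == 0
  lab[mA & S_h >= opts$min_evidence] <- "host"
  lab[mA & todo() & b >= Tq & b > 0] <- "both"
  lab[mA & todo() & 4 * x >= 3 * n] <- "neither"
  lab[mA & todo()] <- "ambiguous"

  # quick branch: no host k-mers at all
  mB <- todo() & (h + hw) == 0
  lab[mB & S_g >= opts$min_evidence] <- "graft"
  lab[mB & todo() & b >= Tq & b > 0] <- "both"
  lab[mB & todo() & 4 * x >= 3 * n] <- "neither"
  lab[mB & todo()] <- "ambiguous"

  # no strong opposite k-mers, few weak opposite, some strong own
  lab[todo() & g == 0 & gw <= opts$few_weak & h >= opts$some_strong] <- "host"
  lab[todo() & h == 0 & hw <= opts$few_weak & g >= opts$some_strong] <- "graft"

  # complex-evidence rules, evaluated jointly to keep host/graft symmetry
  c_host <- todo() & S_h >= Tq & g <= opts$opposite_strong_max &
    opts$weak_ratio * gw <= S_h
  c_graft <- todo() & S_g >= Tq & h <= opts$opposite_strong_max &
    opts$weak_ratio * hw <= S_g
  lab[c_host & c_graft] <- "ambiguous"   # conflicting symmetric evidence
  lab[todo() & c_host] <- "host"
  lab[todo() & c_graft] <- "graft"

  lab[todo() & b >= Tq & b > 0] <- "both"
  lab[todo() & 4 * x >= 3 * n] <- "neither"
  lab[todo()] <- "ambiguous"

  factor(lab, levels = class_labels())
}

#' Per-fragment k-mer statistics
#'
#' Looks up every valid k-mer of a fragment (one read or a read pair;
#' windows containing N are skipped) in the index and counts the
#' categories; mate counts are summed.
#'
#' @param index a `xenosort_index`.
#' @param reads1 character vector of read sequences.
#' @param reads2 optional character vector of mate sequences (same
#'   length).
#' @return data.frame with columns h, hw, g, gw, b, x, n (one row per
#'   fragment).
#' @export
fragment_stats <- function(index, reads1, reads2 = NULL) {
  stopifnot(inherits(index, "xenosort_index"))
  m <- .cpp_fragment_stats(index$store, as.character(reads1),
                           if (is.null(reads2)) NULL else as.character(reads2))
  as.data.frame(m)
}

#' Classify fragments
#'
#' Full classification: k-mer statistics via [fragment_stats()] followed
#' by the rule tree of [classify_stats()].  With `quick = TRUE`, only
#' the third and third-last valid k-mer of each read are sampled first
#' (2 samples for a single read, 4 for a pair); if all sampled
#' categories agree (weak host counting as host, weak graft as graft,
#' absent as neither), the fragment is labeled from that sample alone,
#' otherwise it falls back to full counting.  Reads with fewer than 3
#' valid k-mers always fall back.
#'
#' @inheritParams fragment_stats
#' @param quick sample-first mode (see above).
#' @param opts thresholds from [classify_options()].
#' @return factor of labels, one per fragment.
#' @export
classify_fragments <- function(index, reads1, reads2 = NULL, quick = FALSE,
                               opts = classify_options()) {
  stopifnot(inherits(index, "xenosort_index"))
  r2 <- if (is.null(reads2)) NULL else as.character(reads2)
  if (!quick) {
    return(classify_stats(fragment_stats(index, reads1, reads2), opts))
  }
  samp <- .cpp_quick_sample(index$store, as.character(reads1), r2)
  lab <- rep(NA_character_, length(samp))
  lab[samp == 0] <- "host"
  lab[samp == 1] <- "graft"
  lab[samp == 2] <- "both"
  lab[samp == 3] <- "neither"
  fb <- which(samp < 0)
  if (length(fb)) {
    st <- fragment_stats(index, reads1[fb], if (is.null(r2)) NULL else r2[fb])
    lab[fb] <- as.character(classify_stats(st, opts))
  }
  factor(lab, levels = class_labels())
}
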