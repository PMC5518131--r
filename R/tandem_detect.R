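#' Tandem repeat detection parameters
#'
#' Filters of the alignment-to-self method: minimum percent identity, maximum
#' separation between the midpoints of the two repeat units, the long/short
#' unit-length split, and whether inverted (reverse-strand) self-alignments
#' count as repeats.
#'
#' @param min_identity_pct Minimum alignment identity, percent (default 95).
#' @param max_midpoint_sep Maximum midpoint separation in bases (default 1 Mbp).
#' @param long_unit_threshold Unit length separating long from short repeats,
#'   bases (default 2000).
#' @param include_reverse_strand Keep inverted repeats (default TRUE).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_identity_pct = 95,
                             max_midpoint_sep = 1e6,
                             long_unit_threshold = 2000L,
                             include_reverse_strand = TRUE) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            max_midpoint_sep > 0, long_unit_threshold > 0)
  structure(list(min_identity_pct = min_identity_pct,
                 max_midpoint_sep = max_midpoint_sep,
                 long_unit_threshold = as.integer(long_unit_threshold),
                 include_reverse_strand = isTRUE(include_reverse_strand)),
            class = "detection_params")
}

#' Canonicalize a self-alignment table
#'
#' Keeps only same-sequence alignments, orders each record so the
#' earlier-starting interval comes first (unit1), drops the trivial
#' full-diagonal self-match (identical intervals), and removes the exact
#' duplicates this reordering creates — in particular each A-to-B record's
#' B-to-A mirror.
#'
#' @param aln Alignment `data.frame` (see [alignment_table()]).
#' @return Alignment `data.frame` with `query_id == target_id`, query interval
#'   starting no later than target interval.
#' @export
canonicalize_self_alignments <- function(aln) {
  if (nrow(aln) == 0L) return(alignment_table())
  aln <- aln[aln$query_id == aln$target_id, , drop = FALSE]
  if (nrow(aln) == 0L) return(alignment_table())
  # order the two intervals: unit1 = earlier (start, then end)
  swap <- aln$qstart > aln$tstart | (aln$qstart == aln$tstart & aln$qend > aln$tend)
  qs <- ifelse(swap, aln$tstart, aln$qstart); qe <- ifelse(swap, aln$tend, aln$qend)
  ts <- ifelse(swap, aln$qstart, aln$tstart); te <- ifelse(swap, aln$qend, aln$tend)
  aln$qstart <- qs; aln$qend <- qe; aln$tstart <- ts; aln$tend <- te
  aln$aln_len_target <- aln$tend - aln$tstart
  diagonal <- aln$qstart == aln$tstart & aln$qend == aln$tend
  aln <- aln[!diagonal, , drop = FALSE]
  key <- paste(aln$query_id, aln$qstart, aln$qend, aln$tstart, aln$tend,
               aln$strand, aln$identity_pct, sep = "\r")
  aln <- aln[!duplicated(key), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Detect tandem repeat pairs from a genome self-alignment
#'
#' Applies the alignment-to-self filters to call repeat pairs: same sequence
#' only (mirrors removed), identity at least `min_identity_pct`,
#' non-overlapping repeat units, and midpoint separation at most
#' `max_midpoint_sep`. Midpoints are integer `floor((start + end) / 2)`.
#' Pairs with identical intervals but different identities are deduplicated
#' keeping the higher identity.
#'
#' @param aln Alignment `data.frame`; canonicalization is applied internally
#'   and is idempotent.
#' @param params A [detection_params()] list.
#' @return A `data.frame` of repeat pairs with columns `seq_id`, `start1`,
#'   `end1`, `start2`, `end2`, `strand`, `identity_pct`, `midpoint_sep`,
#'   sorted by `(seq_id, start1, start2)`.
#' @export
detect_tandem_repeats <- function(aln, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  aln <- canonicalize_self_alignments(aln)
  empty <- data.frame(seq_id = character(), start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(), strand = character(),
                      identity_pct = numeric(), midpoint_sep = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  keep <- aln$identity_pct >= params$min_identity_pct
  if (!params$include_reverse_strand) keep <- keep & aln$strand == "+"
  keep <- keep & aln$qend <= aln$tstart                    # units must not overlap
  mid1 <- (aln$qstart + aln$qend) %/% 2L
  mid2 <- (aln$tstart + aln$tend) %/% 2L
  sep <- abs(mid2 - mid1)
  keep <- keep & sep <= params$max_midpoint_sep
  pairs <- data.frame(
    seq_id = aln$query_id[keep],
    start1 = aln$qstart[keep], end1 = aln$qend[keep],
    start2 = aln$tstart[keep], end2 = aln$tend[keep],
    strand = aln$strand[keep], identity_pct = aln$identity_pct[keep],
    midpoint_sep = as.integer(sep[keep]), stringsAsFactors = FALSE
  )
  if (nrow(pairs) == 0L) return(empty)
  # identical interval pairs keep the highest identity
  pairs <- pairs[order(pairs$seq_id, pairs$start1, pairs$start2, pairs$end1,
                       pairs$end2, -pairs$identity_pct), , drop = FALSE]
  key <- paste(pairs$seq_id, pairs$start1, pairs$end1, pairs$start2, pairs$end2,
               pairs$strand, sep = "\r")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  pairs <- pairs[order(pairs$seq_id, pairs$start1, pairs$start2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Re-express repeat pairs as self-alignment records
#'
#' Convenience inverse of [detect_tandem_repeats()] used to check idempotence
#' and to feed pairs back through alignment-based tools.
#'
#' @param pairs Repeat-pair `data.frame`.
#' @return Alignment `data.frame`.
#' @export
pairs_as_alignments <- function(pairs) {
  alignment_table(
    query_id = pairs$seq_id, target_id = pairs$seq_id,
    qstart = pairs$start1, qend = pairs$end1,
    tstart = pairs$start2, tend = pairs$end2,
    strand = pairs$strand, identity_pct = pairs$identity_pct
  )
}

#' Partition repeat pairs into long and short at a unit-length threshold
#'
#' A pair is long iff the *shorter* of its two units is at least
#' `long_unit_threshold` bases — both units must be gene-scale for the pair to
#' count as a long repeat.
#'
#' @param pairs Repeat-pair `data.frame`.
#' @param params A [detection_params()] list.
#' @return List with elements `long` and `short` (disjoint, exhaustive).
#' @export
partition_by_length <- function(pairs, params = detection_params()) {
  if (nrow(pairs) == 0L) return(list(long = pairs, short = pairs))
  min_unit <- pmin(pairs$end1 - pairs$start1, pairs$end2 - pairs$start2)
  is_long <- min_unit >= params$long_unit_threshold
  list(long = pairs[is_long, , drop = FALSE],
       short = pairs[!is_long, , drop = FALSE])
}

#' Size statistics of a repeat collection
#'
#' N50 over the multiset of all repeat unit lengths (two units per pair).
#'
#' @param pairs Repeat-pair `data.frame` (non-empty).
#' @param genome_size Optional reference size for NG50; defaults to the total
#'   unit span (making NG50 equal N50).
#' @return See [assembly_stats()].
#' @export
repeat_collection_stats <- function(pairs, genome_size = NULL) {
  if (nrow(pairs) == 0L) stopf("repeat_collection_stats: no repeat pairs")
  lens <- c(pairs$end1 - pairs$start1, pairs$end2 - pairs$start2)
  assembly_stats(lens, genome_size %||% sum(lens))
}
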