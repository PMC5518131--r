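#' Capture classification parameters
#'
#' @param coverage_threshold Fraction of a repeat unit that must be covered,
#'   strictly exceeded, for the unit to count as captured (default 0.5).
#' @return A list of class `capture_params`.
#' @export
capture_params <- function(coverage_threshold = 0.5) {
  stopifnot(coverage_threshold > 0, coverage_threshold < 1)
  structure(list(coverage_threshold = coverage_threshold), class = "capture_params")
}

#' Fraction of a repeat unit covered by a set of alignments
#'
#' Coverage is the length of the union of the alignments' target intervals
#' intersected with the unit, divided by the unit length. Only alignments
#' whose `target_id` matches the unit's sequence contribute; strand is
#' ignored.
#'
#' @param seq_id Sequence the unit lives on.
#' @param start,end Unit interval, 0-based half-open.
#' @param aln Alignment `data.frame` (assembly query vs reference target).
#' @return Fraction in `[0, 1]`.
#' @export
unit_coverage <- function(seq_id, start, end, aln) {
  if (end <= start) stopf("unit_coverage: zero-length unit")
  sel <- aln$target_id == seq_id
  covered <- interval_union_length(aln$tstart[sel], aln$tend[sel], start, end)
  covered / (end - start)
}

#' Classify how an assembly captures each reference repeat pair
#'
#' For each pair, every assembly scaffold's coverage of the two units is the
#' union of its alignments' target intervals clipped to each unit. A pair is
#' `one_scaffold` when some single scaffold covers more than the threshold of
#' *both* units (checked first); else `two_scaffolds` when two distinct
#' scaffolds each cover more than the threshold of one unit apiece; else
#' `underrepresented`. `single_alignment` flags pairs where one alignment
#' record's target interval alone exceeds the threshold on each unit.
#'
#' When several scaffolds qualify for `one_scaffold`, the one with the larger
#' summed coverage wins, ties broken by lexicographic id.
#'
#' @param pairs Repeat-pair `data.frame` on the reference (see
#'   [detect_tandem_repeats()]).
#' @param aln Alignments with assembly scaffolds as `query_id` and reference
#'   sequences as `target_id`.
#' @param params A [capture_params()] list.
#' @param labels Category labels, in order (one scaffold / two scaffolds /
#'   underrepresented).
#' @return `pairs` with added columns `category`, `scaffold_1`, `scaffold_2`,
#'   `cov1`, `cov2`, `single_alignment`.
#' @export
classify_capture <- function(pairs, aln, params = capture_params(),
                             labels = c("one_scaffold", "two_scaffolds",
                                        "underrepresented")) {
  stopifnot(inherits(params, "capture_params"), length(labels) == 3L)
  thr <- params$coverage_threshold
  n <- nrow(pairs)
  category <- character(n); s1 <- rep(NA_character_, n); s2 <- rep(NA_character_, n)
  cov1 <- numeric(n); cov2 <- numeric(n); single <- logical(n)
  for (i in seq_len(n)) {
    p <- pairs[i, ]
    rel <- aln[aln$target_id == p$seq_id, , drop = FALSE]
    scafs <- sort(unique(rel$query_id))
    c1 <- vapply(scafs, function(s) {
      sel <- rel$query_id == s
      interval_union_length(rel$tstart[sel], rel$tend[sel], p$start1, p$end1) /
        (p$end1 - p$start1)
    }, numeric(1))
    c2 <- vapply(scafs, function(s) {
      sel <- rel$query_id == s
      interval_union_length(rel$tstart[sel], rel$tend[sel], p$start2, p$end2) /
        (p$end2 - p$start2)
    }, numeric(1))
    both <- c1 > thr & c2 > thr
    if (any(both)) {
      cand <- scafs[both]
      best <- cand[order(-(c1[both] + c2[both]), cand)][[1L]]
      category[[i]] <- labels[[1L]]
      s1[[i]] <- best
      cov1[[i]] <- c1[[match(best, scafs)]]; cov2[[i]] <- c2[[match(best, scafs)]]
    } else if (any(c1 > thr) && any(c2 > thr)) {
      a <- scafs[c1 > thr]; a <- a[order(-c1[c1 > thr], a)][[1L]]
      b <- scafs[c2 > thr]; b <- b[order(-c2[c2 > thr], b)][[1L]]
      # a == b would imply that scaffold covers both units, handled above
      category[[i]] <- labels[[2L]]
      s1[[i]] <- a; s2[[i]] <- b
      cov1[[i]] <- c1[[match(a, scafs)]]; cov2[[i]] <- c2[[match(b, scafs)]]
    } else {
      category[[i]] <- labels[[3L]]
      cov1[[i]] <- if (length(c1)) max(c1) else 0
      cov2[[i]] <- if (length(c2)) max(c2) else 0
    }
    # a single record spanning > threshold of each unit
    f1 <- pmin(rel$tend, p$end1) - pmax(rel$tstart, p$start1)
    f2 <- pmin(rel$tend, p$end2) - pmax(rel$tstart, p$start2)
    single[[i]] <- any(f1 / (p$end1 - p$start1) > thr &
                       f2 / (p$end2 - p$start2) > thr)
  }
  out <- pairs
  out$category <- category
  out$scaffold_1 <- s1; out$scaffold_2 <- s2
  out$cov1 <- cov1; out$cov2 <- cov2
  out$single_alignment <- single
  out
}

#' Number of repeat pairs captured within a single alignment
#'
#' @param calls Output of [classify_capture()].
#' @return Count of calls with `single_alignment = TRUE`.
#' @export
count_single_alignment_captures <- function(calls) {
  if (nrow(calls) == 0L) return(0L)
  sum(calls$single_alignment)
}

#' Reciprocal capture assessment (assembly repeats against the reference)
#'
#' The same classification with the roles of reference and assembly reversed:
#' repeat pairs detected on assembly scaffolds are classified by how reference
#' chromosomes cover them. Categories read `one_chromosome`,
#' `two_chromosomes`, `underrepresented`; a `two_chromosomes` call flags a
#' likely false duplication in the assembly.
#'
#' @param assembly_pairs Repeat pairs detected on assembly scaffolds.
#' @param aln Alignments in the usual orientation (assembly scaffolds as
#'   `query_id`, reference sequences as `target_id`); the role swap happens
#'   internally.
#' @param params A [capture_params()] list.
#' @return See [classify_capture()].
#' @export
reciprocal_assessment <- function(assembly_pairs, aln, params = capture_params()) {
  swapped <- alignment_table(
    query_id = aln$target_id, target_id = aln$query_id,
    qstart = aln$tstart, qend = aln$tend,
    tstart = aln$qstart, tend = aln$qend,
    strand = aln$strand, identity_pct = aln$identity_pct
  )
  classify_capture(assembly_pairs, swapped, params,
                   labels = c("one_chromosome", "two_chromosomes",
                              "underrepresented"))
}
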