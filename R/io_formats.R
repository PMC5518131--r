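#' Read a FASTA file
#'
#' Sequences are returned as a named character vector (names are record ids)
#' with bases upper-cased. Record order follows the file.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @details Duplicate ids and zero-length sequences are errors; an empty file
#'   yields an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(dss))
  if (any(!nzchar(ids))) stopf("FASTA record with empty id in %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stopf("duplicate FASTA id: %s", dup[[1L]])
  seqs <- toupper(as.character(dss))
  if (any(nchar(seqs) == 0L))
    stopf("zero-length sequence for id: %s", ids[nchar(seqs) == 0L][[1L]])
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an alignment table
#'
#' The common currency of the toolkit: one row per local alignment between a
#' query and a target sequence, with 0-based half-open intervals on both sides,
#' a strand flag, and percent identity. Reverse-strand alignments are stored
#' with forward (ordered) intervals plus `strand = "-"`.
#'
#' @param query_id,target_id Character vectors of sequence ids.
#' @param qstart,qend,tstart,tend Integer 0-based half-open coordinates.
#' @param strand `"+"` or `"-"` per record.
#' @param identity_pct Percent identity in `[0, 100]`.
#' @return A `data.frame` with one row per alignment and a computed
#'   `aln_len_target` column (target-side span in bases).
#' @export
alignment_table <- function(query_id = character(), target_id = character(),
                            qstart = integer(), qend = integer(),
                            tstart = integer(), tend = integer(),
                            strand = character(), identity_pct = numeric()) {
  df <- data.frame(
    query_id = as.character(query_id), target_id = as.character(target_id),
    qstart = as.integer(qstart), qend = as.integer(qend),
    tstart = as.integer(tstart), tend = as.integer(tend),
    strand = as.character(strand), identity_pct = as.numeric(identity_pct),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0L) {
    if (any(df$qstart >= df$qend) || any(df$tstart >= df$tend))
      stopf("alignment intervals must satisfy start < end")
    if (any(df$identity_pct < 0 | df$identity_pct > 100))
      stopf("identity_pct outside [0,100]")
    if (any(!df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  }
  df$aln_len_target <- df$tend - df$tstart
  df
}

#' Read pairwise alignments (PAF or nucmer show-coords tabular)
#'
#' Coordinates are normalized to 0-based half-open intervals; reverse-strand
#' records (start > end on one side of a coords table) get ordered intervals
#' and `strand = "-"`. PAF identity is computed as
#' `100 * matching bases / alignment block length`.
#'
#' @param path Input file.
#' @param dialect `"paf"` (12+ column PAF) or `"coords"` (show-coords
#'   `-T -l -c` style: 1-based inclusive S1 E1 S2 E2 ... %IDY ... TAGR TAGQ,
#'   where S1/E1 are target/reference coordinates and the last two columns are
#'   the target and query ids).
#' @return An alignment `data.frame` (see [alignment_table()]).
#' @export
read_alignments <- function(path, dialect = c("paf", "coords")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "coords") {
    # tolerate the textual header show-coords prints before the table
    is_data <- grepl("^-?[0-9]+\t", lines)
    lines <- lines[is_data]
  }
  if (length(lines) == 0L) return(alignment_table())
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (dialect == "paf") parse_paf_fields(f, i) else parse_coords_fields(f, i)
  })
  do.call(rbind, parsed)
}

parse_paf_fields <- function(f, line_no) {
  if (length(f) < 12L) stopf("malformed PAF line %d: fewer than 12 columns", line_no)
  num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
  if (anyNA(num)) stopf("malformed PAF line %d: non-numeric coordinate", line_no)
  strand <- f[[5L]]
  if (!strand %in% c("+", "-")) stopf("malformed PAF line %d: bad strand '%s'", line_no, strand)
  nmatch <- as.numeric(f[[10L]]); alen <- as.numeric(f[[11L]])
  if (alen <= 0) stopf("malformed PAF line %d: non-positive block length", line_no)
  idy <- 100 * nmatch / alen
  if (idy < 0 || idy > 100) stopf("identity outside [0,100] at PAF line %d", line_no)
  alignment_table(
    query_id = f[[1L]], target_id = f[[6L]],
    qstart = as.integer(f[[3L]]), qend = as.integer(f[[4L]]),
    tstart = as.integer(f[[8L]]), tend = as.integer(f[[9L]]),
    strand = strand, identity_pct = idy
  )
}

parse_coords_fields <- function(f, line_no) {
  if (length(f) < 9L) stopf("malformed coords line %d: fewer than 9 columns", line_no)
  co <- suppressWarnings(as.integer(f[1:4]))
  if (anyNA(co)) stopf("malformed coords line %d: non-numeric coordinate", line_no)
  idy <- suppressWarnings(as.numeric(f[[7L]]))
  if (is.na(idy)) stopf("malformed coords line %d: non-numeric identity", line_no)
  if (idy < 0 || idy > 100) stopf("identity outside [0,100] at coords line %d", line_no)
  tgt <- f[[length(f) - 1L]]; qry <- f[[length(f)]]
  t_rev <- co[[1L]] > co[[2L]]; q_rev <- co[[3L]] > co[[4L]]
  # 1-based inclusive -> 0-based half-open; a reversed side flags strand "-"
  ts <- min(co[[1L]], co[[2L]]) - 1L; te <- max(co[[1L]], co[[2L]])
  qs <- min(co[[3L]], co[[4L]]) - 1L; qe <- max(co[[3L]], co[[4L]])
  alignment_table(
    query_id = qry, target_id = tgt,
    qstart = qs, qend = qe, tstart = ts, tend = te,
    strand = if (xor(t_rev, q_rev)) "-" else "+", identity_pct = idy
  )
}

#' Write an alignment table
#'
#' Inverse of [read_alignments()] up to dialect-specific rounding: intervals
#' and strand round-trip exactly in both dialects.
#'
#' @param aln Alignment `data.frame`.
#' @param path Output path.
#' @param dialect `"paf"` or `"coords"`.
#' @param query_lengths,target_lengths Optional named vectors of sequence
#'   lengths for the PAF length columns; defaults to each record's end
#'   coordinate (a lower bound).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, dialect = c("paf", "coords"),
                             query_lengths = NULL, target_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (nrow(aln) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  if (dialect == "paf") {
    qlen <- if (is.null(query_lengths)) aln$qend else unname(query_lengths[aln$query_id])
    tlen <- if (is.null(target_lengths)) aln$tend else unname(target_lengths[aln$target_id])
    alen <- pmax(aln$qend - aln$qstart, aln$tend - aln$tstart)
    nmatch <- as.integer(round(aln$identity_pct / 100 * alen))
    lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
                     aln$query_id, qlen, aln$qstart, aln$qend, aln$strand,
                     aln$target_id, tlen, aln$tstart, aln$tend, nmatch, alen)
  } else {
    # minus-strand records reverse the query side, the show-coords convention
    s2 <- ifelse(aln$strand == "-", aln$qend, aln$qstart + 1L)
    e2 <- ifelse(aln$strand == "-", aln$qstart + 1L, aln$qend)
    lines <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                     aln$tstart + 1L, aln$tend, s2, e2,
                     aln$tend - aln$tstart, aln$qend - aln$qstart,
                     aln$identity_pct, aln$target_id, aln$query_id)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Split a scaffold into contigs at long N runs
#'
#' Cuts at every run of at least `min_n_run` consecutive `N`s and removes
#' those runs; shorter N runs are retained inside contigs. Contig ids carry
#' the ordinal and the 0-based scaffold offset (`<id>_c<ordinal>_<offset>`).
#'
#' @param scaffold Length-1 named character vector (one sequence).
#' @param min_n_run Minimum N-run length that triggers a split (default 20).
#' @return Named character vector of contigs, ordered by scaffold position.
#' @export
extract_contigs <- function(scaffold, min_n_run = 20L) {
  stopifnot(length(scaffold) == 1L, min_n_run >= 1L)
  id <- if (is.null(names(scaffold))) "scaffold" else names(scaffold)[[1L]]
  seq <- toupper(scaffold[[1L]])
  pat <- sprintf("N{%d,}", as.integer(min_n_run))
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) {
    out <- stats::setNames(seq, sprintf("%s_c1_0", id))
    return(out[nchar(out) > 0L])
  }
  run_start <- as.integer(m)                      # 1-based
  run_len <- attr(m, "match.length")
  piece_start <- c(1L, run_start + run_len)       # 1-based starts of kept pieces
  piece_end <- c(run_start - 1L, nchar(seq))      # 1-based inclusive ends
  keep <- piece_start <= piece_end
  piece_start <- piece_start[keep]; piece_end <- piece_end[keep]
  if (length(piece_start) == 0L) return(stats::setNames(character(0), character(0)))
  pieces <- substring(seq, piece_start, piece_end)
  names(pieces) <- sprintf("%s_c%d_%d", id, seq_along(pieces), piece_start - 1L)
  pieces
}

#' Assembly size statistics (N50 / NG50)
#'
#' N50 is the length of the sequence that first brings the cumulative sum, in
#' descending length order, to at least half the total span; NG50 uses half of
#' `genome_size` instead, and is 0 when the assembly never reaches it.
#'
#' @param lengths Positive sequence lengths.
#' @param genome_size Genome size in bases for NG50.
#' @return A list with `n_sequences`, `total_span`, `n50`, `ng50`, `max_len`.
#' @export
assembly_stats <- function(lengths, genome_size) {
  if (length(lengths) == 0L) stopf("assembly_stats: empty length list")
  if (any(lengths <= 0)) stopf("assembly_stats: lengths must be > 0")
  if (genome_size <= 0) stopf("assembly_stats: genome_size must be > 0")
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(l)
  n50 <- l[[which(cs >= sum(l) / 2)[[1L]]]]
  hit <- which(cs >= genome_size / 2)
  ng50 <- if (length(hit) == 0L) 0 else l[[hit[[1L]]]]
  list(n_sequences = length(l), total_span = sum(l),
       n50 = n50, ng50 = ng50, max_len = l[[1L]])
}
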