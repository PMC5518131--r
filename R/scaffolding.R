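#' Synthetic mate-pair scaffolding parameters
#'
#' Defaults mirror the hybrid-assembly recipe: up to 200-fold coverage of
#' 2 x 2000 bp pairs per insert class at 10, 40 and 160 Kbp inserts, sampled
#' from guide scaffolds.
#'
#' @param read_len Read length in bases (default 2000).
#' @param insert_sizes Insert classes in bases (default 10e3, 40e3, 160e3).
#' @param coverage_per_insert Target fold coverage per insert class
#'   (default 200).
#' @param insert_sd_frac Insert-size jitter as a fraction of the insert
#'   (default 0.1, normal deviate).
#' @param min_link_support Minimum mate pairs supporting a retained link
#'   (default 2).
#' @param rng_seed Integer seed; sampling is deterministic given the seed.
#' @return A list of class `scaffold_params`.
#' @export
scaffold_params <- function(read_len = 2000L,
                            insert_sizes = c(10000L, 40000L, 160000L),
                            coverage_per_insert = 200,
                            insert_sd_frac = 0.1,
                            min_link_support = 2L,
                            rng_seed = 1L) {
  stopifnot(read_len >= 1, all(insert_sizes > 2 * read_len),
            coverage_per_insert > 0, insert_sd_frac >= 0, min_link_support >= 1)
  structure(list(read_len = as.integer(read_len),
                 insert_sizes = as.integer(insert_sizes),
                 coverage_per_insert = coverage_per_insert,
                 insert_sd_frac = insert_sd_frac,
                 min_link_support = as.integer(min_link_support),
                 rng_seed = as.integer(rng_seed)),
            class = "scaffold_params")
}

#' Scaffold quality-control parameters
#'
#' @param min_reads_per_scaffold Scaffolds with fewer reads are removed
#'   (default 15; a 15-read scaffold is retained).
#' @param min_split_coverage Positions with coverage below this are deleted,
#'   splitting the scaffold (default 2; exactly 2-fold coverage survives).
#' @param min_piece_len Pieces shorter than this are dropped (default 200).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_reads_per_scaffold = 15L, min_split_coverage = 2L,
                      min_piece_len = 200L) {
  stopifnot(min_reads_per_scaffold >= 1, min_split_coverage >= 1,
            min_piece_len >= 1)
  structure(list(min_reads_per_scaffold = as.integer(min_reads_per_scaffold),
                 min_split_coverage = as.integer(min_split_coverage),
                 min_piece_len = as.integer(min_piece_len)),
            class = "qc_params")
}

#' Sample synthetic long-range mate pairs from guide scaffolds
#'
#' Per scaffold and insert class, `floor(coverage * L / (2 * read_len))`
#' pairs are drawn with uniform start positions and normal insert jitter
#' (`sd = insert_sd_frac * insert`). Mates are innie: the second read is the
#' reverse complement of the scaffold's forward strand. Pairs that would
#' extend past a scaffold end are skipped, as are pairs with a read over 50%
#' N.
#'
#' @param scaffolds Named character vector of guide scaffold sequences.
#' @param params A [scaffold_params()] list.
#' @return `data.frame` with columns `pair_id`, `origin`, `insert_class`,
#'   `start1`, `end1`, `start2`, `end2` (0-based half-open positions on the
#'   origin scaffold), `seq1`, `seq2`.
#' @export
sample_synthetic_mates <- function(scaffolds, params = scaffold_params()) {
  stopifnot(inherits(params, "scaffold_params"))
  rl <- params$read_len
  out <- list()
  with_seed(params$rng_seed, {
    for (sid in names(scaffolds)) {
      sq <- scaffolds[[sid]]
      L <- nchar(sq)
      for (ins in params$insert_sizes) {
        if (L < ins) next
        n <- floor(params$coverage_per_insert * L / (2 * rl))
        if (n < 1L) next
        insert <- as.integer(round(stats::rnorm(n, ins, params$insert_sd_frac * ins)))
        start <- as.integer(floor(stats::runif(n, 0, L)))
        ok <- insert >= 2L * rl & start + insert <= L
        if (!any(ok)) next
        insert <- insert[ok]; start <- start[ok]
        s1 <- start; e1 <- start + rl
        s2 <- start + insert - rl; e2 <- start + insert
        seq1 <- substring(sq, s1 + 1L, e1)
        seq2 <- reverse_complement(substring(sq, s2 + 1L, e2))
        n_frac1 <- nchar(gsub("[^Nn]", "", seq1)) / rl
        n_frac2 <- nchar(gsub("[^Nn]", "", seq2)) / rl
        keep <- n_frac1 <= 0.5 & n_frac2 <= 0.5
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
          pair_id = sprintf("%s_i%d_p%d", sid, ins, which(keep)),
          origin = sid, insert_class = ins,
          start1 = s1[keep], end1 = e1[keep],
          start2 = s2[keep], end2 = e2[keep],
          seq1 = seq1[keep], seq2 = seq2[keep],
          stringsAsFactors = FALSE)
      }
    }
  })
  if (length(out) == 0L)
    return(data.frame(pair_id = character(), origin = character(),
                      insert_class = integer(), start1 = integer(),
                      end1 = integer(), start2 = integer(), end2 = integer(),
                      seq1 = character(), seq2 = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# k-mer index of a contig set: position list per k-mer (forward strand only;
# reads are searched in both orientations instead)
build_kmer_index <- function(contigs, k) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (cid in names(contigs)) {
    sq <- contigs[[cid]]
    n <- nchar(sq)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(sq, starts, starts + k - 1L)
    sp <- split(starts - 1L, kmers)
    for (km in names(sp)) {
      cur <- idx[[km]]
      entry <- list(list(cid = cid, pos = sp[[km]]))
      idx[[km]] <- if (is.null(cur)) entry else c(cur, entry)
    }
  }
  idx
}

# all exact full-length placements of one read (already oriented) given the index
exact_hits <- function(read, contigs, idx, k) {
  anchor <- substr(read, 1L, k)
  cand <- idx[[anchor]]
  hits <- list()
  if (!is.null(cand)) {
    rl <- nchar(read)
    for (entry in cand) {
      sq <- contigs[[entry$cid]]
      for (p in entry$pos) {
        if (p + rl <= nchar(sq) && substr(sq, p + 1L, p + rl) == read)
          hits[[length(hits) + 1L]] <- list(cid = entry$cid, pos = p)
      }
    }
  }
  hits
}

#' Map synthetic mate reads to contigs by unique exact placement
#'
#' Each read is anchored via its leading k-mer in a k-mer index of the contigs
#' and extended to a full-length exact comparison, on both strands. A read is
#' placed iff it has exactly one full-length placement across all contigs and
#' strands; ambiguous or absent reads are reported unmapped.
#'
#' @param pairs Mate table from [sample_synthetic_mates()].
#' @param contigs Named character vector of contig sequences.
#' @param k Anchor k-mer size (default 31).
#' @return `data.frame` with one row per read: `pair_id`, `mate` (1 or 2),
#'   `contig`, `pos` (0-based start), `strand`, `mapped` (logical; unmapped
#'   reads have NA placement columns).
#' @export
map_mates_exact <- function(pairs, contigs, k = 31L) {
  if (length(contigs) == 0L) stopf("map_mates_exact: no contigs")
  contigs <- toupper(contigs)
  idx <- build_kmer_index(contigs, k)
  n <- nrow(pairs)
  # interleave mate-1/mate-2 reads; reverse complements computed in one
  # vectorized call rather than per read
  reads <- toupper(as.vector(rbind(pairs$seq1, pairs$seq2)))
  rc_reads <- if (n > 0L) reverse_complement(reads) else character(0)
  contig <- rep(NA_character_, 2L * n); pos <- rep(NA_integer_, 2L * n)
  strand <- rep(NA_character_, 2L * n); mapped <- rep(FALSE, 2L * n)
  for (ix in seq_len(2L * n)) {
    fw <- exact_hits(reads[[ix]], contigs, idx, k)
    rc <- exact_hits(rc_reads[[ix]], contigs, idx, k)
    if (length(fw) + length(rc) != 1L) next
    h <- if (length(fw) == 1L) fw[[1L]] else rc[[1L]]
    contig[[ix]] <- h$cid; pos[[ix]] <- h$pos
    strand[[ix]] <- if (length(fw) == 1L) "+" else "-"
    mapped[[ix]] <- TRUE
  }
  data.frame(pair_id = rep(pairs$pair_id, each = 2L),
             mate = rep(1:2, times = n),
             contig = contig, pos = pos, strand = strand, mapped = mapped,
             stringsAsFactors = FALSE)
}

#' Bundle mate placements into contig-joining links
#'
#' Pairs whose two reads map to different contigs are grouped by the pair of
#' (contig, facing end) they connect. A read placed on the forward strand
#' faces its contig's right end; on the reverse strand, its left end (innie
#' mates point toward the gap). Each group becomes one link with
#' `gap_estimate` the median over pairs of
#' `insert - distance(read1 to facing end) - distance(read2 to facing end)`
#' (possibly negative for overlapping contigs); groups with fewer than
#' `min_link_support` pairs are dropped.
#'
#' @param pairs Mate table from [sample_synthetic_mates()].
#' @param placements Read placements from [map_mates_exact()].
#' @param contigs Named character vector (lengths are needed).
#' @param params A [scaffold_params()] list.
#' @return `data.frame` with columns `contig_a`, `end_a` (`"L"`/`"R"`),
#'   `contig_b`, `end_b`, `gap_estimate`, `support`, ordered by decreasing
#'   support then ids.
#' @export
bundle_links <- function(pairs, placements, contigs, params = scaffold_params()) {
  stopifnot(inherits(params, "scaffold_params"))
  rl <- params$read_len
  clen <- stats::setNames(nchar(contigs), names(contigs))
  pl <- placements[placements$mapped, , drop = FALSE]
  p1 <- pl[pl$mate == 1L, c("pair_id", "contig", "pos", "strand")]
  p2 <- pl[pl$mate == 2L, c("pair_id", "contig", "pos", "strand")]
  names(p1)[2:4] <- c("c1", "pos1", "st1")
  names(p2)[2:4] <- c("c2", "pos2", "st2")
  df <- merge(merge(pairs[, c("pair_id", "insert_class")], p1, by = "pair_id"),
              p2, by = "pair_id")
  df <- df[df$c1 != df$c2, , drop = FALSE]
  empty <- data.frame(contig_a = character(), end_a = character(),
                      contig_b = character(), end_b = character(),
                      gap_estimate = numeric(), support = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)
  # facing end and distance from the read's outer edge to that end
  end1 <- ifelse(df$st1 == "+", "R", "L")
  d1 <- ifelse(df$st1 == "+", clen[df$c1] - df$pos1, df$pos1 + rl)
  end2 <- ifelse(df$st2 == "+", "R", "L")
  d2 <- ifelse(df$st2 == "+", clen[df$c2] - df$pos2, df$pos2 + rl)
  gap <- df$insert_class - d1 - d2
  # canonical order within a link: lexicographically smaller contig first
  first <- df$c1 < df$c2 | (df$c1 == df$c2 & end1 <= end2)
  ca <- ifelse(first, df$c1, df$c2); ea <- ifelse(first, end1, end2)
  cb <- ifelse(first, df$c2, df$c1); eb <- ifelse(first, end2, end1)
  key <- paste(ca, ea, cb, eb, sep = "\r")
  agg <- lapply(split(seq_along(key), key), function(ix) {
    data.frame(contig_a = ca[ix[[1L]]], end_a = ea[ix[[1L]]],
               contig_b = cb[ix[[1L]]], end_b = eb[ix[[1L]]],
               gap_estimate = stats::median(gap[ix]),
               support = length(ix), stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, agg)
  links <- links[links$support >= params$min_link_support, , drop = FALSE]
  if (nrow(links) == 0L) return(empty)
  links <- links[order(-links$support, links$contig_a, links$contig_b,
                       links$end_a, links$end_b), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Greedy scaffold layout from bundled links
#'
#' Links are processed in decreasing support (ties by lexicographic contig
#' ids, then ends); a link is accepted iff both facing contig ends are still
#' free and acceptance would not close a cycle (union-find). Accepted links
#' chain contigs into paths which are emitted as layouts; every unlinked
#' contig becomes a singleton layout. Orientation within a path follows the
#' joined ends (entering a contig at its left end means forward orientation);
#' each path starts at its lexicographically smallest terminal contig, so
#' output is deterministic up to that convention.
#'
#' @param contigs Named character vector of contig sequences.
#' @param links Link `data.frame` from [bundle_links()].
#' @param gap_floor Minimum emitted gap in bases (default 20, so that contig
#'   re-extraction at a 20-N rule inverts scaffolding).
#' @return `data.frame` with columns `layout_id`, `ordinal`, `contig`,
#'   `orientation` (`"+"`/`"-"`), `gap_after` (NA on the last contig of each
#'   layout).
#' @export
layout_scaffolds <- function(contigs, links, gap_floor = 20L) {
  ids <- names(contigs)
  occupied <- new.env(parent = emptyenv())      # "contig\rend" -> link row
  parent <- stats::setNames(seq_along(ids), ids)
  # iterative union-find over contig ids
  find <- function(x) {
    repeat {
      p <- parent[[x]]
      if (ids[[p]] == x) return(x)
      x <- ids[[p]]
    }
  }
  accepted <- list()
  if (nrow(links) > 0L) {
    ord <- order(-links$support, links$contig_a, links$contig_b,
                 links$end_a, links$end_b)
    for (r in ord) {
      lk <- links[r, ]
      if (!lk$contig_a %in% ids || !lk$contig_b %in% ids) next
      ka <- paste0(lk$contig_a, "\r", lk$end_a)
      kb <- paste0(lk$contig_b, "\r", lk$end_b)
      if (!is.null(occupied[[ka]]) || !is.null(occupied[[kb]])) next
      ra <- find(lk$contig_a); rb <- find(lk$contig_b)
      if (ra == rb) next                        # would close a cycle
      parent[[ra]] <- match(rb, ids)
      occupied[[ka]] <- lk; occupied[[kb]] <- lk
      accepted[[length(accepted) + 1L]] <- lk
    }
  }
  # adjacency: for each contig end, the accepted link leaving it
  link_at <- function(cid, end) occupied[[paste0(cid, "\r", end)]]
  emitted <- stats::setNames(rep(FALSE, length(ids)), ids)
  layouts <- list(); lid <- 0L
  # path terminals: contigs with at least one free end; walk from the smaller id
  walk <- function(start_contig, enter_end) {
    path <- list()
    cid <- start_contig; enter <- enter_end
    repeat {
      ori <- if (enter == "L") "+" else "-"
      exit <- if (enter == "L") "R" else "L"
      lk <- link_at(cid, exit)
      gap <- if (is.null(lk)) NA_real_
             else max(as.numeric(lk$gap_estimate), gap_floor)
      path[[length(path) + 1L]] <- list(contig = cid, orientation = ori, gap = gap)
      emitted[[cid]] <<- TRUE
      if (is.null(lk)) break
      nxt <- if (lk$contig_a == cid && lk$end_a == exit)
        c(lk$contig_b, lk$end_b) else c(lk$contig_a, lk$end_a)
      cid <- nxt[[1L]]; enter <- nxt[[2L]]
    }
    path
  }
  for (cid in sort(ids)) {
    if (emitted[[cid]]) next
    free_l <- is.null(link_at(cid, "L")); free_r <- is.null(link_at(cid, "R"))
    if (!free_l && !free_r) next               # interior contig, reached later
    enter <- if (free_l) "L" else "R"
    lid <- lid + 1L
    path <- walk(cid, enter)
    layouts[[lid]] <- data.frame(
      layout_id = sprintf("layout_%03d", lid),
      ordinal = seq_along(path),
      contig = vapply(path, `[[`, character(1), "contig"),
      orientation = vapply(path, `[[`, character(1), "orientation"),
      gap_after = vapply(path, `[[`, numeric(1), "gap"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, layouts)
}

#' Render layouts to scaffold sequences
#'
#' Gaps become N runs of `max(gap_estimate, gap_floor)` bases, so
#' [extract_contigs()] with `min_n_run = 20` recovers the contigs.
#'
#' @param layouts Output of [layout_scaffolds()].
#' @param contigs Named character vector.
#' @param gap_floor Minimum N-run length (default 20).
#' @return Named character vector of scaffold sequences.
#' @export
layout_to_fasta <- function(layouts, contigs, gap_floor = 20L) {
  out <- character(0)
  for (id in unique(layouts$layout_id)) {
    rows <- layouts[layouts$layout_id == id, , drop = FALSE]
    rows <- rows[order(rows$ordinal), , drop = FALSE]
    parts <- character(0)
    for (r in seq_len(nrow(rows))) {
      sq <- contigs[[rows$contig[[r]]]]
      if (rows$orientation[[r]] == "-") sq <- reverse_complement(sq)
      parts <- c(parts, sq)
      if (r < nrow(rows)) {
        gap <- rows$gap_after[[r]]
        gap <- if (is.na(gap)) gap_floor else max(round(gap), gap_floor)
        parts <- c(parts, strrep("N", gap))
      }
    }
    out[[id]] <- paste(parts, collapse = "")
  }
  out
}

#' Per-base coverage from read placements
#'
#' Difference-array accumulation: coverage at position i is the number of
#' placements containing i.
#'
#' @param placements `data.frame` with `start`, `end` (0-based half-open),
#'   already restricted to one sequence.
#' @param seq_len Sequence length.
#' @return Integer vector of length `seq_len` (coverage at 0-based positions
#'   0 .. seq_len-1).
#' @export
coverage_profile <- function(placements, seq_len) {
  if (nrow(placements) > 0L &&
      (any(placements$start < 0) || any(placements$end > seq_len)))
    stopf("placement out of bounds")
  d <- integer(seq_len + 1L)
  if (nrow(placements) > 0L) {
    inc <- tabulate(placements$start + 1L, nbins = seq_len + 1L)
    dec <- tabulate(placements$end + 1L, nbins = seq_len + 1L)
    d <- inc - dec
  }
  cumsum(d)[seq_len(seq_len)]
}

#' Filter low-support scaffolds and split at low-coverage positions
#'
#' Scaffolds with fewer than `min_reads_per_scaffold` placements are removed.
#' In the survivors, every position with coverage below `min_split_coverage`
#' is deleted and the maximal retained runs are emitted as new sequences;
#' pieces shorter than `min_piece_len` are dropped. Output names carry
#' provenance: `<scaffold>_p<ordinal>_<offset>`.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param placements `data.frame` with `seq_id`, `start`, `end`.
#' @param params A [qc_params()] list.
#' @return Named character vector of surviving (possibly split) sequences.
#' @export
filter_and_split_scaffolds <- function(scaffolds, placements,
                                       params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  out <- character(0)
  for (sid in names(scaffolds)) {
    pl <- placements[placements$seq_id == sid, , drop = FALSE]
    if (nrow(pl) < params$min_reads_per_scaffold) next
    sq <- scaffolds[[sid]]
    cov <- coverage_profile(pl, nchar(sq))
    keep <- cov >= params$min_split_coverage
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ord <- 0L
    for (i in seq_along(r$values)) {
      if (!r$values[[i]]) next
      if (r$lengths[[i]] < params$min_piece_len) next
      ord <- ord + 1L
      out[[sprintf("%s_p%d_%d", sid, ord, starts[[i]] - 1L)]] <-
        substr(sq, starts[[i]], ends[[i]])
    }
  }
  out
}
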