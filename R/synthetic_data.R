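#' Specification of one planted tandem array
#'
#' @param unit_len Repeat unit length in bases.
#' @param copies Number of tandem copies (at least 2).
#' @param spacer_len Bases between consecutive copies.
#' @param divergence Per-base substitution rate applied independently to each
#'   copy, in `[0, 0.05]`. Substitutions only (no indels), so pairwise
#'   identity between copies is computable exactly by Hamming comparison.
#' @param position 0-based offset of the array in the background sequence.
#' @return A list of class `array_spec`.
#' @export
array_spec <- function(unit_len, copies, spacer_len, divergence = 0,
                       position = 0L) {
  stopifnot(unit_len >= 1, copies >= 2, spacer_len >= 0,
            divergence >= 0, divergence <= 0.05, position >= 0)
  structure(list(unit_len = as.integer(unit_len), copies = as.integer(copies),
                 spacer_len = as.integer(spacer_len), divergence = divergence,
                 position = as.integer(position)),
            class = "array_spec")
}

array_span <- function(spec) {
  spec$copies * spec$unit_len + (spec$copies - 1L) * spec$spacer_len
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[[i]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[i]]), 1L)
  paste(ch, collapse = "")
}

hamming_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(x) == length(y))
  100 * sum(x == y) / length(x)
}

#' Generate a genome with planted tandem arrays and its ground truth
#'
#' The background is i.i.d. uniform DNA; each array is `copies` independently
#' mutated copies of a random master unit separated by random spacers,
#' spliced into the background at its specified position (replacing
#' background bases). Everything is deterministic given the seed.
#'
#' @param background_len Genome length in bases.
#' @param specs List of [array_spec()] objects; realized arrays must not
#'   overlap.
#' @param seed Integer seed.
#' @param genome_id Sequence id of the generated genome.
#' @return A `truth_set` list: `genome` (named character vector), `arrays`
#'   (per array: `spec`, `units` data.frame of realized 0-based half-open
#'   intervals, `copy_seqs`), and `expected_pairs` — the repeat pairs the
#'   default detection filters must recover (copy-vs-copy pairs at >= 95%
#'   Hamming identity and <= 1 Mbp midpoint separation).
#' @export
make_genome_with_arrays <- function(background_len, specs, seed,
                                    genome_id = "genome1") {
  stopifnot(background_len >= 1, length(specs) >= 1)
  lapply(specs, function(s) stopifnot(inherits(s, "array_spec")))
  spans <- vapply(specs, array_span, integer(1))
  starts <- vapply(specs, `[[`, integer(1), "position")
  ends <- starts + spans
  if (any(ends > background_len)) stopf("array extends past background end")
  o <- order(starts)
  if (any(starts[o][-1L] < ends[o][-length(o)])) stopf("planted arrays overlap")
  dparams <- detection_params()
  with_seed(seed, {
    genome <- random_dna(background_len)
    arrays <- vector("list", length(specs))
    pair_rows <- list()
    for (ai in seq_along(specs)) {
      sp <- specs[[ai]]
      master <- random_dna(sp$unit_len)
      copies <- vapply(seq_len(sp$copies),
                       function(i) mutate_seq(master, sp$divergence),
                       character(1))
      step <- sp$unit_len + sp$spacer_len
      ustart <- sp$position + (seq_len(sp$copies) - 1L) * step
      uend <- ustart + sp$unit_len
      parts <- character(0)
      for (i in seq_len(sp$copies)) {
        parts <- c(parts, copies[[i]])
        if (i < sp$copies) parts <- c(parts, random_dna(sp$spacer_len))
      }
      arr_seq <- paste(parts, collapse = "")
      substr(genome, sp$position + 1L, sp$position + nchar(arr_seq)) <- arr_seq
      arrays[[ai]] <- list(spec = sp,
                           units = data.frame(start = ustart, end = uend),
                           copy_seqs = copies)
      for (i in seq_len(sp$copies - 1L)) for (j in (i + 1L):sp$copies) {
        idy <- hamming_identity(copies[[i]], copies[[j]])
        sep <- abs(((ustart[[j]] + uend[[j]]) %/% 2L) -
                     ((ustart[[i]] + uend[[i]]) %/% 2L))
        if (idy >= dparams$min_identity_pct && sep <= dparams$max_midpoint_sep)
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            seq_id = genome_id, start1 = ustart[[i]], end1 = uend[[i]],
            start2 = ustart[[j]], end2 = uend[[j]], strand = "+",
            identity_pct = idy, midpoint_sep = as.integer(sep),
            array = ai, copy1 = i, copy2 = j, stringsAsFactors = FALSE)
      }
    }
    expected <- if (length(pair_rows) == 0L)
      data.frame(seq_id = character(), start1 = integer(), end1 = integer(),
                 start2 = integer(), end2 = integer(), strand = character(),
                 identity_pct = numeric(), midpoint_sep = integer(),
                 array = integer(), copy1 = integer(), copy2 = integer(),
                 stringsAsFactors = FALSE)
    else do.call(rbind, pair_rows)
    expected <- expected[order(expected$start1, expected$start2), , drop = FALSE]
    rownames(expected) <- NULL
    structure(list(genome = stats::setNames(genome, genome_id),
                   genome_id = genome_id, arrays = arrays,
                   expected_pairs = expected),
              class = "truth_set")
  })
}

#' Emit the analytic self-alignment of a planted-array genome
#'
#' Produces what a self-aligner would report: the trivial full-length
#' diagonal, every copy-vs-copy alignment within each array (identity from
#' exact Hamming comparison of the realized copies), and the B-to-A mirror of
#' each — deliberately exercising canonicalization downstream.
#'
#' @param truth A `truth_set` from [make_genome_with_arrays()].
#' @return Alignment `data.frame`: `1 + 2 * sum(choose(copies, 2))` records.
#' @export
emit_self_alignments <- function(truth) {
  stopifnot(inherits(truth, "truth_set"))
  L <- nchar(truth$genome[[1L]])
  gid <- truth$genome_id
  rows <- list(alignment_table(gid, gid, 0L, L, 0L, L, "+", 100))
  for (arr in truth$arrays) {
    k <- nrow(arr$units)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      idy <- hamming_identity(arr$copy_seqs[[i]], arr$copy_seqs[[j]])
      u1 <- arr$units[i, ]; u2 <- arr$units[j, ]
      rows[[length(rows) + 1L]] <- alignment_table(
        gid, gid, u1$start, u1$end, u2$start, u2$end, "+", idy)
      rows[[length(rows) + 1L]] <- alignment_table(      # the mirror
        gid, gid, u2$start, u2$end, u1$start, u1$end, "+", idy)
    }
  }
  do.call(rbind, rows)
}

#' Corrupt a planted-array genome into an assembly with known capture truth
#'
#' Three operators realize the three repeat-capture categories:
#' \describe{
#'   \item{collapse}{the target array is reduced to its first copy in a
#'     single scaffold; the retained copy aligns onto every planted copy's
#'     reference interval (the best alignment available for those positions),
#'     so the array's pairs are expected `one_scaffold`.}
#'   \item{fragment}{the genome is cut between the first and second copy into
#'     two scaffolds with purely colinear alignments; pairs straddling the
#'     cut are expected `two_scaffolds`.}
#'   \item{delete_unit}{one copy is excised and only colinear alignments are
#'     emitted, leaving that unit uncovered; its pairs are expected
#'     `underrepresented`.}
#' }
#' Pairs not touched by the operator are expected `one_scaffold`.
#'
#' @param truth A `truth_set`.
#' @param op `"collapse"`, `"fragment"` or `"delete_unit"`.
#' @param array Index of the target planted array.
#' @param unit Copy index for `delete_unit` (default 2).
#' @return List with `assembly` (named character vector), `alignments`
#'   (assembly query vs reference target) and `expected` (the truth's
#'   expected pairs plus an `expected_category` column).
#' @export
corrupt_assembly <- function(truth, op = c("collapse", "fragment", "delete_unit"),
                             array = 1L, unit = 2L) {
  stopifnot(inherits(truth, "truth_set"))
  op <- match.arg(op)
  if (array < 1L || array > length(truth$arrays)) stopf("unknown array: %d", array)
  arr <- truth$arrays[[array]]
  units <- arr$units
  genome <- truth$genome[[1L]]
  L <- nchar(genome)
  gid <- truth$genome_id
  expected <- truth$expected_pairs
  in_target <- expected$array == array

  delete_interval <- function(del_s, del_e, asm_id) {
    asm <- paste0(substr(genome, 1L, del_s), substring(genome, del_e + 1L))
    aln <- list()
    if (del_s > 0L)
      aln[[1L]] <- alignment_table(asm_id, gid, 0L, del_s, 0L, del_s, "+", 100)
    if (del_e < L)
      aln[[length(aln) + 1L]] <- alignment_table(
        asm_id, gid, del_s, del_s + (L - del_e), del_e, L, "+", 100)
    list(asm = stats::setNames(asm, asm_id), aln = do.call(rbind, aln))
  }

  if (op == "collapse") {
    del_s <- units$end[[1L]]
    del_e <- units$end[[nrow(units)]]
    res <- delete_interval(del_s, del_e, "asm1")
    aln <- res$aln
    # repeat-induced placements of the retained copy onto every planted copy
    for (i in seq_len(nrow(units))) {
      idy <- hamming_identity(arr$copy_seqs[[1L]], arr$copy_seqs[[i]])
      aln <- rbind(aln, alignment_table(
        "asm1", gid, units$start[[1L]], units$end[[1L]],
        units$start[[i]], units$end[[i]], "+", idy))
    }
    expected$expected_category <- "one_scaffold"
    return(list(assembly = res$asm, alignments = aln, expected = expected))
  }

  if (op == "fragment") {
    if (arr$spec$copies < 2L) stopf("fragment needs >= 2 copies")
    cut <- units$end[[1L]] + max(arr$spec$spacer_len %/% 2L, 0L)
    asm <- c(asm1 = substr(genome, 1L, cut), asm2 = substring(genome, cut + 1L))
    aln <- rbind(
      alignment_table("asm1", gid, 0L, cut, 0L, cut, "+", 100),
      alignment_table("asm2", gid, 0L, L - cut, cut, L, "+", 100))
    cat_of <- ifelse(in_target &
                       (expected$start1 < cut) != (expected$start2 < cut),
                     "two_scaffolds", "one_scaffold")
    expected$expected_category <- cat_of
    return(list(assembly = asm, alignments = aln, expected = expected))
  }

  # delete_unit
  if (unit < 1L || unit > nrow(units)) stopf("unknown unit: %d", unit)
  res <- delete_interval(units$start[[unit]], units$end[[unit]], "asm1")
  hit <- in_target & (expected$copy1 == unit | expected$copy2 == unit)
  expected$expected_category <- ifelse(hit, "underrepresented", "one_scaffold")
  list(assembly = res$asm, alignments = res$aln, expected = expected)
}

#' Simulate uniform long-read placements over a sequence
#'
#' @param seq_length Sequence length in bases.
#' @param coverage Target mean fold coverage.
#' @param read_len Read length (reads are fully contained, so realized mean
#'   coverage is `round(coverage * seq_length / read_len) * read_len /
#'   seq_length`).
#' @param seed Integer seed.
#' @param seq_id Sequence id recorded on the placements.
#' @return `data.frame` with `read_id`, `seq_id`, `start`, `end`.
#' @export
simulate_long_read_placements <- function(seq_length, coverage, read_len, seed,
                                          seq_id = "seq1") {
  stopifnot(read_len <= seq_length, coverage >= 0)
  n <- round(coverage * seq_length / read_len)
  if (n == 0L)
    return(data.frame(read_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    start <- as.integer(floor(stats::runif(n, 0, seq_length - read_len + 1)))
    data.frame(read_id = sprintf("read_%06d", seq_len(n)), seq_id = seq_id,
               start = start, end = start + as.integer(read_len),
               stringsAsFactors = FALSE)
  })
}

#' Generate a gene table, similarity hits and expected tandem clusters
#'
#' Families are placed as consecutive gene runs on one scaffold, separated by
#' three unrelated singleton genes (more than any tandem spacing rule
#' allows), with TE annotations interleaved inside families at the requested
#' density. Hits connect all members within a family at a uniformly low
#' E-value and never cross families, so the expected tandem clusters are the
#' families themselves.
#'
#' @param n_arrays Number of gene families.
#' @param family_sizes Family sizes, recycled across `n_arrays`.
#' @param te_density Probability of inserting a TE between consecutive family
#'   members.
#' @param seed Integer seed.
#' @return List with `genes` ([gene_table()]), `hits` (`a`, `b`, `evalue`)
#'   and `expected_sizes` (sorted family sizes, the expected tandem-cluster
#'   sizes).
#' @export
make_gene_fixture <- function(n_arrays, family_sizes, te_density = 0, seed = 1L) {
  stopifnot(n_arrays >= 1, all(family_sizes >= 2), te_density >= 0,
            te_density <= 1)
  sizes <- rep_len(as.integer(family_sizes), n_arrays)
  gene_len <- 1000L; gap <- 500L
  with_seed(seed, {
    ids <- character(0); starts <- integer(0); te <- logical(0)
    pos <- 0L; sep_n <- 0L; te_n <- 0L
    add_gene <- function(id, is_te) {
      ids <<- c(ids, id); starts <<- c(starts, pos); te <<- c(te, is_te)
      pos <<- pos + gene_len + gap
    }
    hits <- list()
    for (f in seq_len(n_arrays)) {
      members <- sprintf("fam%02d_g%02d", f, seq_len(sizes[[f]]))
      for (m in seq_along(members)) {
        add_gene(members[[m]], FALSE)
        if (m < length(members) && stats::runif(1) < te_density) {
          te_n <- te_n + 1L
          add_gene(sprintf("te_%03d", te_n), TRUE)
        }
      }
      for (i in seq_len(sizes[[f]] - 1L)) for (j in (i + 1L):sizes[[f]])
        hits[[length(hits) + 1L]] <- data.frame(
          a = members[[i]], b = members[[j]], evalue = 1e-50,
          stringsAsFactors = FALSE)
      if (f < n_arrays) for (s in 1:3) {
        sep_n <- sep_n + 1L
        add_gene(sprintf("sep_%03d", sep_n), FALSE)
      }
    }
    genes <- gene_table(ids, "chr1", starts, starts + gene_len,
                        strand = "+", is_te = te)
    list(genes = genes, hits = do.call(rbind, hits),
         expected_sizes = sort(sizes))
  })
}
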