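# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# N50/NG50 by direct scan of descending prefix sums
oracle_n50 <- function(lengths, half) {
  l <- sort(lengths, decreasing = TRUE)
  s <- 0
  for (x in l) {
    s <- s + x
    if (s >= half) return(x)
  }
  0
}

# length of union of 0-based half-open intervals clipped to [lo, hi),
# by position marking
oracle_union_len <- function(starts, ends, lo, hi) {
  if (hi <= lo) return(0L)
  hitpos <- rep(FALSE, hi - lo)
  for (k in seq_along(starts)) {
    s <- max(starts[[k]], lo); e <- min(ends[[k]], hi)
    if (s < e) hitpos[(s - lo + 1L):(e - lo)] <- TRUE
  }
  sum(hitpos)
}

# connected components of an undirected edge list, by label propagation
oracle_components <- function(a, b) {
  nodes <- sort(unique(c(a, b)))
  lab <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_along(a)) {
      m <- min(lab[[a[[k]]]], lab[[b[[k]]]])
      if (lab[[a[[k]]]] != m || lab[[b[[k]]]] != m) {
        lab[[a[[k]]]] <- m; lab[[b[[k]]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(nodes, lab)
}

# all exact occurrences of a read across contigs and strands, by fixed-string
# search
oracle_placements <- function(read, contigs) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hits <- list()
  for (cid in names(contigs)) {
    for (st in c("+", "-")) {
      pat <- if (st == "+") read else rc
      m <- gregexpr(pat, contigs[[cid]], fixed = TRUE)[[1L]]
      if (m[[1L]] != -1L) for (p in as.integer(m))
        hits[[length(hits) + 1L]] <- list(cid = cid, pos = p - 1L, strand = st)
    }
  }
  hits
}

# tandem-pair rule applied by direct enumeration over all gene pairs
oracle_tandem_pairs <- function(genes, clusters, max_intervening = 1L) {
  memb <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                          unlist(clusters))
  out <- character(0)
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, ]
    g <- g[order(g$start), ]
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
      if (i >= j) next
      gi <- g[i, ]; gj <- g[j, ]
      if (gi$is_te || gj$is_te) next
      ci <- memb[gi$gene_id]; cj <- memb[gj$gene_id]
      if (is.na(ci) || is.na(cj) || ci != cj) next
      between <- g$start > gi$start & g$start < gj$start & !g$is_te
      if (sum(between) <= max_intervening)
        out <- c(out, paste(gi$gene_id, gj$gene_id, sep = "|"))
    }
  }
  sort(out)
}

# random alignment table generator for round-trip fuzzing
random_alignments <- function(n, n_seqs = 4L, max_coord = 5000L) {
  sid <- sprintf("seq%02d", seq_len(n_seqs))
  q <- sample(sid, n, replace = TRUE)
  t <- sample(sid, n, replace = TRUE)
  # widths >= 2: a width-1 interval cannot express strand in the 1-based
  # inclusive coords dialect
  qs <- sample.int(max_coord - 2L, n); qe <- qs + 1L + sample.int(500L, n)
  ts <- sample.int(max_coord - 2L, n); te <- ts + 1L + sample.int(500L, n)
  alignment_table(q, t, qs, qe, ts, te,
                  sample(c("+", "-"), n, replace = TRUE),
                  round(stats::runif(n, 80, 100), 2))
}

# a small standard truth set: two planted arrays on a 40 kb background
small_truth <- function(seed = 101, divergence = 0) {
  make_genome_with_arrays(
    40000,
    list(array_spec(3000, 2, 1000, divergence, 5000),
         array_spec(500, 3, 200, divergence, 20000)),
    seed = seed)
}
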