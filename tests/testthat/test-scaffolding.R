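test_that("mate sampling honours the coverage formula, bounds and the seed", {
  set.seed(1)
  guide <- c(g1 = paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE),
                        collapse = ""))
  sp <- scaffold_params(read_len = 500, insert_sizes = 10000L,
                        coverage_per_insert = 50, rng_seed = 3)
  mates <- sample_synthetic_mates(guide, sp)
  n_target <- floor(50 * 100000 / (2 * 500))
  expect_lte(nrow(mates), n_target)
  expect_gte(nrow(mates), n_target * 0.8)            # end effects only
  # sampled bases approximate the requested coverage
  expect_equal(nrow(mates) * 2 * 500 / 100000, 50, tolerance = 0.15)
  # all reads inside the scaffold, innie orientation round-trips the sequence
  expect_true(all(mates$start1 >= 0 & mates$end2 <= 100000))
  i <- which.max(mates$end2 - mates$start1)
  expect_equal(mates$seq1[[i]],
               substr(guide[[1]], mates$start1[[i]] + 1, mates$end1[[i]]))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mates$seq2[[i]])))
  expect_equal(rc, substr(guide[[1]], mates$start2[[i]] + 1, mates$end2[[i]]))

  # determinism
  expect_identical(mates, sample_synthetic_mates(guide, sp))

  # insert exceeding the scaffold yields no pairs for that class
  sp2 <- scaffold_params(read_len = 500, insert_sizes = 160000L,
                         coverage_per_insert = 50, rng_seed = 3)
  expect_equal(nrow(sample_synthetic_mates(guide, sp2)), 0L)

  # reads over 50% N are discarded
  guide_n <- c(g2 = paste0(strrep("A", 3000), strrep("N", 94000),
                           strrep("T", 3000)))
  sp3 <- scaffold_params(read_len = 500, insert_sizes = 10000L,
                         coverage_per_insert = 5, rng_seed = 3)
  mn <- sample_synthetic_mates(guide_n, sp3)
  if (nrow(mn) > 0) {
    nfrac <- nchar(gsub("[^N]", "", mn$seq1)) / 500
    expect_true(all(nfrac <= 0.5))
  }
})

test_that("exact mapping places unique reads and agrees with substring search", {
  set.seed(4)
  contigs <- stats::setNames(
    vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = ""),
      character(1)),
    c("cA", "cB", "cC"))
  # a verbatim interior read maps to its source
  read <- substr(contigs[["cB"]], 501, 560)
  pairs <- data.frame(pair_id = "p1", origin = "x", insert_class = 1000L,
                      start1 = 0L, end1 = 60L, start2 = 0L, end2 = 60L,
                      seq1 = read, seq2 = read, stringsAsFactors = FALSE)
  pl <- map_mates_exact(pairs, contigs, k = 31)
  expect_true(all(pl$mapped))
  expect_equal(pl$contig, c("cB", "cB"))
  expect_equal(pl$pos, c(500L, 500L))
  # mate 2 is searched as stored; its strand reflects the orientation found
  expect_equal(pl$strand, c("+", "+"))

  # a read present in two contigs is ambiguous
  dup <- paste0(substr(contigs[["cA"]], 1, 60))
  contigs2 <- c(contigs, cD = paste0("TTTT", dup, "GGGG"))
  pairs$seq1 <- dup; pairs$seq2 <- dup
  pl <- map_mates_exact(pairs, contigs2, k = 31)
  expect_false(any(pl$mapped))

  # randomized agreement with the brute-force oracle
  for (rep in 1:20) {
    if (runif(1) < 0.7) {
      cid <- sample(names(contigs), 1)
      s <- sample(1:2900, 1)
      rd <- substr(contigs[[cid]], s, s + 59)
      if (runif(1) < 0.5)
        rd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
    } else {
      rd <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    }
    pairs$seq1 <- rd; pairs$seq2 <- rd
    pl <- map_mates_exact(pairs, contigs, k = 31)
    hits <- oracle_placements(rd, contigs)
    if (length(hits) == 1L) {
      expect_true(pl$mapped[[1]])
      expect_equal(pl$contig[[1]], hits[[1]]$cid)
      expect_equal(pl$pos[[1]], hits[[1]]$pos)
      expect_equal(pl$strand[[1]], hits[[1]]$strand)
    } else {
      expect_false(pl$mapped[[1]])
    }
  }
})

test_that("link bundling estimates planted gaps and enforces support", {
  cs <- make_linear_case(2, gap_range = c(5000, 5000), seed = 6)
  sp <- scaffold_params(read_len = 300, insert_sizes = 10000L,
                        coverage_per_insert = 30, insert_sd_frac = 0.05,
                        rng_seed = 7)
  mates <- sample_synthetic_mates(cs$genome, sp)
  pl <- map_mates_exact(mates, cs$contigs)
  links <- bundle_links(mates, pl, cs$contigs, sp)
  expect_equal(nrow(links), 1L)
  expect_equal(links$contig_a, "ctg01"); expect_equal(links$end_a, "R")
  expect_equal(links$contig_b, "ctg02"); expect_equal(links$end_b, "L")
  expect_equal(links$gap_estimate, 5000, tolerance = 0.1)

  # support below the threshold drops the link
  sp_hi <- scaffold_params(read_len = 300, insert_sizes = 10000L,
                           coverage_per_insert = 30, insert_sd_frac = 0.05,
                           rng_seed = 7,
                           min_link_support = links$support + 1L)
  expect_equal(nrow(bundle_links(mates, pl, cs$contigs, sp_hi)), 0L)

  # intra-contig pairs alone produce no links
  one <- cs$contigs[1]
  pl1 <- map_mates_exact(mates, one)
  expect_equal(nrow(bundle_links(mates, pl1, one, sp)), 0L)
})

test_that("greedy layout recovers a linear genome up to global reversal", {
  cs <- make_linear_case(4, seed = 8)
  sp <- scaffold_params(read_len = 300, insert_sizes = 10000L,
                        coverage_per_insert = 30, insert_sd_frac = 0.05,
                        rng_seed = 9)
  mates <- sample_synthetic_mates(cs$genome, sp)
  pl <- map_mates_exact(mates, cs$contigs)
  links <- bundle_links(mates, pl, cs$contigs, sp)
  lay <- layout_scaffolds(cs$contigs, links)
  expect_equal(length(unique(lay$layout_id)), 1L)
  got <- lay$contig[order(lay$ordinal)]
  truth <- names(cs$contigs)
  expect_true(identical(got, truth) || identical(got, rev(truth)))
  expect_true(all(lay$orientation == "+") || all(lay$orientation == "-"))
  # occupancy: no contig appears twice
  expect_equal(anyDuplicated(lay$contig), 0L)

  # no links: every contig is a singleton layout
  lay0 <- layout_scaffolds(cs$contigs, links[0, ])
  expect_equal(nrow(lay0), length(cs$contigs))
  expect_equal(length(unique(lay0$layout_id)), length(cs$contigs))

  # conflicting links for one end: higher support wins
  fake <- data.frame(
    contig_a = c("ctg01", "ctg01"), end_a = c("R", "R"),
    contig_b = c("ctg02", "ctg03"), end_b = c("L", "L"),
    gap_estimate = c(100, 100), support = c(10L, 3L),
    stringsAsFactors = FALSE)
  lay2 <- layout_scaffolds(cs$contigs[1:3], fake)
  joined <- lay2$layout_id[match(c("ctg01", "ctg02"), lay2$contig)]
  expect_equal(joined[[1]], joined[[2]])
  expect_false(lay2$layout_id[lay2$contig == "ctg03"] %in% joined)

  # rendering and re-extracting contigs inverts scaffolding
  scafs <- layout_to_fasta(lay, cs$contigs)
  back <- extract_contigs(scafs[1], min_n_run = 20)
  ori <- lay$orientation[order(lay$ordinal)]
  want <- vapply(seq_along(got), function(i) {
    sq <- cs$contigs[[got[[i]]]]
    if (ori[[i]] == "-")
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    sq
  }, character(1))
  expect_identical(unname(back), unname(want))
})

test_that("coverage profiles accumulate by difference arrays", {
  pl <- data.frame(read_id = "r1", seq_id = "s", start = 0L, end = 100L)
  cov <- coverage_profile(pl, 200)
  expect_equal(cov, c(rep(1L, 100), rep(0L, 100)))
  expect_equal(coverage_profile(pl[0, ], 50), rep(0L, 50))
  expect_error(coverage_profile(data.frame(start = -1L, end = 5L), 50),
               "out of bounds")
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    st <- sample(0:180, n, replace = TRUE)
    pl <- data.frame(start = st, end = st + sample(1:20, n, replace = TRUE))
    cov <- coverage_profile(pl, 200)
    expect_equal(sum(cov), sum(pl$end - pl$start))
  }
})

test_that("QC removes sub-15-read scaffolds and splits below 2X coverage", {
  sc <- c(s1 = strrep("ACGT", 500))   # 2000 bp
  mk_pl <- function(n, sid = "s1")
    data.frame(read_id = sprintf("r%d", 1:n), seq_id = sid,
               start = rep(0L, n), end = rep(2000L, n))
  expect_length(filter_and_split_scaffolds(sc, mk_pl(14)), 0L)
  expect_length(filter_and_split_scaffolds(sc, mk_pl(15)), 1L)

  # uniform exactly-2X coverage is untouched (boundary is "less than 2X")
  two_x <- mk_pl(16)
  out <- filter_and_split_scaffolds(sc, two_x[1:16, ])
  expect_equal(unname(out), unname(sc))

  # an interior 1X window splits the scaffold into exactly two pieces:
  # 7 reads on each flank (7X) and one read bridging the middle (1X there)
  dip <- rbind(
    data.frame(read_id = sprintf("L%d", 1:7), seq_id = "s1",
               start = 0L, end = 900L),
    data.frame(read_id = sprintf("R%d", 1:7), seq_id = "s1",
               start = 1100L, end = 2000L),
    data.frame(read_id = "M1", seq_id = "s1", start = 900L, end = 1100L))
  out <- filter_and_split_scaffolds(sc, dip)
  expect_length(out, 2L)
  expect_equal(names(out), c("s1_p1_0", "s1_p2_1100"))
  expect_equal(nchar(out), c(900L, 900L), ignore_attr = TRUE)
  # base conservation: output equals input minus low-coverage positions
  cov <- coverage_profile(dip, 2000)
  expect_equal(sum(nchar(out)), sum(cov >= 2))

  # short pieces are dropped
  qp <- qc_params(min_piece_len = 1000L)
  expect_length(filter_and_split_scaffolds(sc, dip, qp), 0L)
})
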