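# build a genome as alternating contigs and gaps with known sizes, so the
# contigs, their order and the gap lengths are all ground truth
make_linear_case <- function(n_contigs, contig_range = c(4000, 9000),
                             gap_range = c(1000, 7000), seed = 1) {
  with_seed(seed, {
    clen <- contig_range[[1]] +
      sample.int(contig_range[[2]] - contig_range[[1]] + 1L, n_contigs,
                 replace = TRUE) - 1L
    gaps <- gap_range[[1]] +
      sample.int(gap_range[[2]] - gap_range[[1]] + 1L, n_contigs - 1L,
                 replace = TRUE) - 1L
    contigs <- stats::setNames(
      vapply(clen, function(n)
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
        character(1)),
      sprintf("ctg%02d", seq_len(n_contigs)))
    parts <- character(0)
    for (i in seq_len(n_contigs)) {
      parts <- c(parts, contigs[[i]])
      if (i < n_contigs)
        parts <- c(parts, paste(sample(c("A", "C", "G", "T"), gaps[[i]],
                                       replace = TRUE), collapse = ""))
    }
    list(genome = c(g1 = paste(parts, collapse = "")), contigs = contigs,
         gaps = gaps)
  })
}
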