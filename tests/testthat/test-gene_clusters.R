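test_that("similarity graph repairs zero E-values, merges hits, drops self-hits", {
  g <- build_similarity_graph(data.frame(
    a = c("g1", "g2"), b = c("g2", "g3"), evalue = c(0, 1e-50)))
  expect_equal(g$evalue, c(1e-50, 1e-50))
  expect_equal(g$weight[[1]], g$weight[[2]])
  expect_equal(g$weight[[1]], 50)

  g <- build_similarity_graph(data.frame(a = "g1", b = "g1", evalue = 1e-80))
  expect_equal(nrow(g), 0L)

  g <- build_similarity_graph(data.frame(
    a = c("a", "b"), b = c("b", "a"), evalue = c(1e-10, 1e-20)))
  expect_equal(nrow(g), 1L)
  expect_equal(g$evalue, 1e-20)
  # merge result does not depend on hit order
  g2 <- build_similarity_graph(data.frame(
    a = c("b", "a"), b = c("a", "b"), evalue = c(1e-20, 1e-10)))
  expect_equal(g, g2)

  expect_error(build_similarity_graph(
    data.frame(a = c("a", "b"), b = c("b", "c"), evalue = c(0, 0))),
    "all E-values are zero")
})

test_that("MCL partitions nodes and separates weakly joined cliques", {
  # disconnected edges can never merge
  e <- data.frame(a = c("a", "c"), b = c("b", "d"), evalue = 1e-10,
                  weight = 10)
  cl <- mcl_cluster(e)
  expect_equal(unname(cl), list(c("a", "b"), c("c", "d")))

  # an equal-weight triangle converges to a single cluster
  tri <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                    evalue = 1e-10, weight = 10)
  expect_equal(unname(mcl_cluster(tri)), list(c("a", "b", "c")))

  # two triangles joined by a 100x weaker bridge split into two clusters
  e2 <- data.frame(a = c("a", "a", "b", "d", "d", "e", "c"),
                   b = c("b", "c", "c", "e", "f", "f", "d"),
                   evalue = 1e-10,
                   weight = c(10, 10, 10, 10, 10, 10, 0.1))
  cl <- mcl_cluster(e2)
  expect_equal(unname(cl), list(c("a", "b", "c"), c("d", "e", "f")))

  # isolated nodes come back as singletons
  cl <- mcl_cluster(tri, nodes = c("z", "a"))
  expect_true(list("z") %in% unname(cl))
})

test_that("MCL output is a partition and never crosses components", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    ids <- sprintf("n%02d", 1:n)
    m <- sample(2:(2 * n), 1)
    a <- sample(ids, m, replace = TRUE); b <- sample(ids, m, replace = TRUE)
    keep <- a != b
    if (!any(keep)) next
    hits <- data.frame(a = a[keep], b = b[keep],
                       evalue = 10^-sample(5:80, sum(keep), replace = TRUE))
    edges <- build_similarity_graph(hits)
    cl <- suppressWarnings(mcl_cluster(edges, nodes = ids))
    # partition of all nodes
    expect_setequal(unlist(cl), ids)
    expect_equal(anyDuplicated(unlist(cl)), 0L)
    # no cluster spans two connected components
    comp <- oracle_components(edges$a, edges$b)
    comp_of <- stats::setNames(rep(seq_along(comp), lengths(comp)),
                               unlist(comp))
    for (members in cl) {
      members <- intersect(members, names(comp_of))
      if (length(members) > 1)
        expect_equal(length(unique(comp_of[members])), 1L)
    }
  }
})

test_that("tandem pair calling follows the one-intervening-non-TE-gene rule", {
  mk <- function(ids, te, cl) {
    genes <- gene_table(ids, "s1", seq_along(ids) * 1000,
                        seq_along(ids) * 1000 + 500, is_te = te)
    call_tandem_pairs(genes, cl)
  }
  # adjacent co-clustered genes pair
  p <- mk(c("A", "B"), c(FALSE, FALSE), list(c("A", "B")))
  expect_equal(nrow(p), 1L)
  # two intervening non-TE genes block the pair
  p <- mk(c("A", "x", "y", "B"), rep(FALSE, 4), list(c("A", "B")))
  expect_equal(nrow(p), 0L)
  # a TE does not count as intervening
  p <- mk(c("A", "te1", "x", "B"), c(FALSE, TRUE, FALSE, FALSE),
          list(c("A", "B")))
  expect_equal(nrow(p), 1L)
  # TEs never become pair members even when co-clustered
  p <- mk(c("A", "te1"), c(FALSE, TRUE), list(c("A", "te1")))
  expect_equal(nrow(p), 0L)
  # duplicate positions are rejected
  genes <- gene_table(c("A", "B"), "s1", c(0, 0) + c(0, 0), c(500, 500))
  expect_error(call_tandem_pairs(genes, list(c("A", "B"))),
               "duplicate gene positions")
})

test_that("pair calling agrees with brute force over small configurations", {
  set.seed(21)
  for (n in 2:7) {
    for (rep in 1:30) {
      ids <- sprintf("g%d", 1:n)
      te <- sample(c(TRUE, FALSE), n, replace = TRUE)
      genes <- gene_table(ids, "s1", (1:n) * 100, (1:n) * 100 + 50, is_te = te)
      # random 2-cluster assignment
      assign <- sample(1:2, n, replace = TRUE)
      clusters <- split(ids, assign)
      got <- call_tandem_pairs(genes, clusters)
      got_keys <- sort(paste(got$gene1, got$gene2, sep = "|"))
      expect_identical(got_keys, oracle_tandem_pairs(genes, clusters))
      # invariance under input shuffling
      perm <- sample(n)
      got2 <- call_tandem_pairs(genes[perm, ], clusters)
      expect_identical(sort(paste(got2$gene1, got2$gene2, sep = "|")),
                       got_keys)
    }
  }
})

test_that("tandem clusters are the connected components of the pair graph", {
  p <- data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"), scaffold = "s1")
  tc <- tandem_clusters(p)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$size, 3L)
  expect_equal(tc$members, "A,B,C")

  p <- data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"), scaffold = "s1")
  tc <- tandem_clusters(p)
  expect_equal(tc$size, c(2L, 2L))

  set.seed(31)
  for (rep in 1:30) {
    n <- sample(3:15, 1)
    m <- sample(1:12, 1)
    a <- sprintf("g%d", sample(n, m, replace = TRUE))
    b <- sprintf("g%d", sample(n, m, replace = TRUE))
    keep <- a != b
    if (!any(keep)) next
    p <- data.frame(gene1 = a[keep], gene2 = b[keep], scaffold = "s1")
    tc <- tandem_clusters(p)
    comp <- oracle_components(p$gene1, p$gene2)
    expect_equal(sort(tc$size), sort(unname(lengths(comp))))
    expect_true(all(tc$size >= 2L))
  }
})

test_that("cluster size histogram conserves total gene count", {
  tc <- data.frame(cluster_id = 1:3, size = c(2L, 2L, 3L),
                   members = c("a,b", "c,d", "e,f,g"), scaffolds = "s1")
  h <- cluster_size_histogram(tc)
  expect_equal(h, data.frame(size = c(2L, 3L), n_clusters = c(2L, 1L)))
  expect_equal(sum(h$size * h$n_clusters), sum(tc$size))
  expect_equal(nrow(cluster_size_histogram(tc[0, ])), 0L)
})
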