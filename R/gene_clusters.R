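#' Clustering parameters for tandem gene-cluster identification
#'
#' @param inflation Markov-clustering inflation exponent (default 2.0,
#'   granularity knob; must exceed 1).
#' @param expansion Matrix-power expansion exponent (default 2).
#' @param max_iter Iteration cap (default 100).
#' @param convergence_tol Maximum entry change declaring convergence
#'   (default 1e-6).
#' @param max_intervening Maximum number of intervening non-TE genes allowed
#'   between the two members of a tandem pair (default 1).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(inflation = 2.0, expansion = 2L, max_iter = 100L,
                           convergence_tol = 1e-6, max_intervening = 1L) {
  stopifnot(inflation > 1, expansion >= 2, max_iter >= 1,
            convergence_tol > 0, max_intervening >= 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 max_intervening = as.integer(max_intervening)),
            class = "cluster_params")
}

#' Gene table constructor
#'
#' @param gene_id,scaffold Character vectors.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`/`"-"`.
#' @param is_te Logical: transposable-element flag (TEs are excluded from
#'   intervening-gene counts and never form pairs).
#' @return A validated `data.frame`.
#' @export
gene_table <- function(gene_id, scaffold, start, end,
                       strand = "+", is_te = FALSE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   is_te = rep_len(as.logical(is_te), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stopf("gene_table: start must be < end")
  if (anyDuplicated(df$gene_id)) stopf("gene_table: duplicate gene_id")
  df
}

#' Build a similarity graph from all-vs-all protein hits
#'
#' E-values of exactly 0 are replaced by the smallest non-zero E-value in the
#' input (they carry no resolvable magnitude of their own). Self-hits are
#' dropped; reciprocal hits are merged keeping the better (lower) E-value.
#' Edge weight defaults to `-log10(E-value)`; with `transform = "score"` a
#' `score` column in `hits` is used directly.
#'
#' @param hits `data.frame` with columns `a`, `b`, `evalue` (and `score` for
#'   the raw-score mode).
#' @param transform `"neglog10"` (default) or `"score"`.
#' @return `data.frame` of edges `a`, `b`, `evalue`, `weight` with `a < b`.
#' @export
build_similarity_graph <- function(hits, transform = c("neglog10", "score")) {
  transform <- match.arg(transform)
  stopifnot(all(c("a", "b", "evalue") %in% names(hits)))
  hits <- hits[hits$a != hits$b, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(a = character(), b = character(), evalue = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE))
  if (any(hits$evalue < 0)) stopf("negative E-value")
  nz <- hits$evalue[hits$evalue > 0]
  if (any(hits$evalue == 0)) {
    if (length(nz) == 0L)
      stopf("all E-values are zero; replacement value undefined")
    hits$evalue[hits$evalue == 0] <- min(nz)
  }
  a <- pmin(hits$a, hits$b); b <- pmax(hits$a, hits$b)
  sc <- if (transform == "score") {
    stopifnot("score" %in% names(hits))
    as.numeric(hits$score)
  } else NULL
  o <- order(a, b, hits$evalue)
  a <- a[o]; b <- b[o]; ev <- hits$evalue[o]; if (!is.null(sc)) sc <- sc[o]
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(a = a[first], b = b[first], evalue = ev[first],
                    stringsAsFactors = FALSE)
  out$weight <- if (transform == "score") sc[first] else -log10(out$evalue)
  if (any(!is.finite(out$weight))) stopf("non-finite edge weight")
  out
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' Builds the column-stochastic transition matrix with self-loops (loop weight
#' equal to the node's maximum incident edge weight; 1 for isolated nodes) and
#' alternates expansion (matrix power `expansion`) with inflation (entrywise
#' power `inflation` followed by column renormalization) until the largest
#' entry change drops below `convergence_tol` or `max_iter` is reached.
#' Entries below 1e-9 are pruned each iteration to keep the matrix sparse.
#' Clusters are read from attractor rows (non-negligible diagonal mass); a
#' node reachable from several attractors joins the lexicographically
#' smallest attractor's cluster, so the result is a deterministic partition
#' of all nodes (singletons allowed).
#'
#' @param edges Edge `data.frame` from [build_similarity_graph()].
#' @param params A [cluster_params()] list.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated.
#' @return Named list of clusters; each element a sorted character vector of
#'   gene ids. Names are the lexicographically smallest member.
#' @export
mcl_cluster <- function(edges, params = cluster_params(), nodes = NULL) {
  stopifnot(inherits(params, "cluster_params"))
  ids <- sort(unique(c(edges$a, edges$b, nodes)))
  n <- length(ids)
  if (n == 0L) return(stats::setNames(list(), character(0)))
  i <- match(edges$a, ids); j <- match(edges$b, ids)
  w <- edges$weight
  if (any(w < 0)) stopf("mcl_cluster: negative weights")
  loop <- rep(1, n)
  if (length(w) > 0) {
    mx <- tapply(c(w, w), c(i, j), max)
    loop[as.integer(names(mx))] <- pmax(as.numeric(mx), 1e-12)
  }
  M <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
                            x = c(w, w, loop), dims = c(n, n))
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  prune <- function(M, eps = 1e-9) {
    M <- Matrix::drop0(M)
    if (length(M@x) > 0 && any(M@x < eps)) {
      M@x[M@x < eps] <- 0
      M <- Matrix::drop0(M)
    }
    M
  }
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    prev <- M
    P <- M
    for (e in seq_len(params$expansion - 1L)) P <- P %*% M   # expansion
    P@x <- P@x ^ params$inflation                            # inflation
    M <- prune(normalize(P))
    if (max(abs(M - prev)) < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", params$max_iter,
            " iterations; interpreting current matrix")
  M <- as(M, "CsparseMatrix")
  attractors <- which(Matrix::diag(M) > 1e-6)
  assign_to <- integer(n)
  S <- Matrix::summary(M)
  for (col in seq_len(n)) {
    rows <- S$i[S$j == col & S$x > 1e-6]
    hit <- intersect(rows, attractors)
    assign_to[[col]] <- if (length(hit) > 0L) min(hit) else col
  }
  # attractor systems spread mass over several attractor rows of one block;
  # merge attractors that attract each other so each block is one cluster
  reps <- assign_to
  repeat {
    new <- reps[reps]
    if (identical(new, reps)) break
    reps <- new
  }
  split_ids <- split(ids, ids[reps])
  out <- lapply(split_ids, function(v) sort(v))
  names(out) <- vapply(out, `[[`, character(1), 1L)
  out[order(names(out))]
}

#' Call tandem gene pairs from clusters and gene order
#'
#' Two genes form a tandem pair iff they are in the same cluster, on the same
#' scaffold, and separated by at most `max_intervening` non-TE genes in start
#' order. TE genes never contribute to the intervening count and never form
#' pairs themselves.
#'
#' @param genes Gene `data.frame` (see [gene_table()]).
#' @param clusters Partition of gene ids (list of character vectors), e.g.
#'   from [mcl_cluster()].
#' @param params A [cluster_params()] list (`max_intervening` is used).
#' @return `data.frame` with columns `gene1`, `gene2` (gene1 earlier on the
#'   scaffold), `scaffold`, sorted by scaffold and position.
#' @export
call_tandem_pairs <- function(genes, clusters, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (anyDuplicated(paste(genes$scaffold, genes$start)))
    stopf("duplicate gene positions on a scaffold")
  memb <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                          unlist(clusters))
  out <- list()
  for (sc in sort(unique(genes$scaffold))) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    non_te <- g[!g$is_te, , drop = FALSE]
    m <- nrow(non_te)
    if (m < 2L) next
    cl <- memb[non_te$gene_id]
    for (i in seq_len(m - 1L)) {
      # only the next max_intervening + 1 non-TE genes can qualify
      for (j in (i + 1L):min(m, i + 1L + params$max_intervening)) {
        if (!is.na(cl[[i]]) && !is.na(cl[[j]]) && cl[[i]] == cl[[j]]) {
          out[[length(out) + 1L]] <- data.frame(
            gene1 = non_te$gene_id[[i]], gene2 = non_te$gene_id[[j]],
            scaffold = sc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene1 = character(), gene2 = character(),
                      scaffold = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Tandem gene clusters as connected components of the pair graph
#'
#' @param pairs Output of [call_tandem_pairs()].
#' @return `data.frame` with one row per cluster: `cluster_id`, `size`,
#'   `members` (comma-joined sorted gene ids), `scaffolds` (comma-joined).
#'   Every cluster has size at least 2.
#' @export
tandem_clusters <- function(pairs) {
  empty <- data.frame(cluster_id = integer(), size = integer(),
                      members = character(), scaffolds = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(pairs[, c("gene1", "gene2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  scaff_of <- stats::setNames(c(pairs$scaffold, pairs$scaffold),
                              c(pairs$gene1, pairs$gene2))
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[[`, character(1), 1L))]
  data.frame(
    cluster_id = seq_along(members),
    size = lengths(members),
    members = vapply(members, paste, character(1), collapse = ","),
    scaffolds = vapply(members, function(m)
      paste(sort(unique(scaff_of[m])), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Histogram of tandem-cluster sizes
#'
#' @param clusters Output of [tandem_clusters()].
#' @return `data.frame` with columns `size` and `n_clusters`; total clustered
#'   genes equal `sum(size * n_clusters)`.
#' @export
cluster_size_histogram <- function(clusters) {
  if (nrow(clusters) == 0L)
    return(data.frame(size = integer(), n_clusters = integer()))
  tab <- table(clusters$size)
  data.frame(size = as.integer(names(tab)), n_clusters = as.integer(tab))
}
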