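#' Build a gene co-expression graph
#'
#' Computes pairwise Pearson correlations between genes on the training
#' matrix and keeps the `edge_budget` edges of largest absolute correlation;
#' edge weights are `|r|`, which keeps the symmetric-normalized propagation
#' well defined.  Constant genes contribute zero correlation.
#'
#' @param train_matrix numeric matrix, training samples x genes.
#' @param edge_budget maximum number of (undirected) edges kept.
#' @return a `correlation_graph`: sparse symmetric `adjacency` with zero
#'   diagonal, `edge_budget`, and an empty list of `coarsening_maps`.
#' @export
build_correlation_graph <- function(train_matrix, edge_budget) {
  if (edge_budget < 1L) stop_config("edge_budget must be >= 1")
  R <- suppressWarnings(stats::cor(train_matrix))
  R[!is.finite(R)] <- 0
  A <- abs(R)
  diag(A) <- 0
  G <- ncol(A)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  w <- A[ut]
  keep <- order(w, decreasing = TRUE)[seq_len(min(edge_budget, sum(w > 0)))]
  keep <- keep[w[keep] > 0]
  adj <- Matrix::sparseMatrix(i = ut[keep, 1L], j = ut[keep, 2L],
                              x = w[keep], dims = c(G, G), symmetric = TRUE)
  adj <- methods::as(Matrix::forceSymmetric(adj), "generalMatrix")
  dimnames(adj) <- list(colnames(train_matrix), colnames(train_matrix))
  structure(list(adjacency = adj, edge_budget = as.integer(edge_budget),
                 coarsening_maps = list()),
            class = "correlation_graph")
}

#' One level of greedy heavy-edge-matching coarsening
#'
#' Scans edges in decreasing weight order and merges each still-unmatched
#' pair of endpoints into one node; leftovers become singletons.  Edge
#' weights between merged nodes are the sums of the constituent weights, and
#' the node-merge map is recorded so features can be max-pooled over the
#' merged pairs.  After one level the node count is at least half the
#' original (every merge involves exactly two nodes).
#'
#' @param graph a `correlation_graph`.
#' @return the coarsened `correlation_graph`, with the new merge map appended
#'   to `coarsening_maps`.  Each map is a list with `cluster` (old node ->
#'   new node), `first`/`second` (member indices per new node, `second` is
#'   `NA` for singletons).
#' @export
coarsen_graph <- function(graph) {
  A <- graph$adjacency
  G <- nrow(A)
  if (G < 2L) stop_config("need at least 2 nodes to coarsen")
  T3 <- Matrix::summary(Matrix::triu(A, k = 1L))
  ord <- order(T3$x, decreasing = TRUE)
  matched <- logical(G)
  cluster <- integer(G)
  nxt <- 0L
  for (e in ord) {
    i <- T3$i[e]; j <- T3$j[e]
    if (!matched[i] && !matched[j]) {
      nxt <- nxt + 1L
      cluster[c(i, j)] <- nxt
      matched[c(i, j)] <- TRUE
    }
  }
  for (v in which(!matched)) {
    nxt <- nxt + 1L
    cluster[v] <- nxt
  }
  first <- integer(nxt); second <- rep(NA_integer_, nxt)
  for (v in seq_len(G)) {
    cl <- cluster[v]
    if (first[cl] == 0L) first[cl] <- v else second[cl] <- v
  }
  S <- Matrix::summary(methods::as(A, "TsparseMatrix"))
  ci <- cluster[S$i]; cj <- cluster[S$j]
  off <- ci != cj
  A2 <- if (any(off)) {
    Matrix::sparseMatrix(i = ci[off], j = cj[off], x = S$x[off],
                         dims = c(nxt, nxt))
  } else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nxt, nxt))
  map <- list(cluster = cluster, first = first, second = second)
  structure(list(adjacency = A2, edge_budget = graph$edge_budget,
                 coarsening_maps = c(graph$coarsening_maps, list(map))),
            class = "correlation_graph")
}

# Symmetric-normalized propagation operator D^{-1/2} (A + I) D^{-1/2},
# returned dense for fast batched multiplication.
normalized_propagation <- function(A) {
  At <- A + Matrix::Diagonal(nrow(A))
  d <- 1 / sqrt(Matrix::rowSums(At))
  as.matrix(Matrix::Diagonal(x = d) %*% At %*% Matrix::Diagonal(x = d))
}
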