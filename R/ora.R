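#' Hypergeometric enrichment of a gene list in one gene set
#'
#' One-sided upper-tail test: with `M` universe genes, `K` of them in the
#' gene set and a list of `n` genes overlapping the set in `k`, the p-value
#' is `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`, computed by exact tail
#' summation of the hypergeometric mass.
#'
#' @param top_genes character vector of list genes (must lie in `universe`).
#' @param gene_set character vector of set genes (intersected with the
#'   universe before testing).
#' @param universe character vector of background genes.
#' @return list with `k`, `K`, `n`, `M`, `p`.
#' @export
hypergeometric_enrichment <- function(top_genes, gene_set, universe) {
  if (!length(universe)) stop_format("empty universe")
  if (!all(top_genes %in% universe))
    stop_format("gene list contains genes outside the universe")
  set_in <- intersect(gene_set, universe)
  M <- length(universe); K <- length(set_in); n <- length(top_genes)
  k <- length(intersect(top_genes, set_in))
  p <- sum(stats::dhyper(k:min(n, K), K, M - K, n))
  list(k = k, K = K, n = n, M = M, p = min(p, 1))
}

#' Over-representation report across ranking methods
#'
#' For each method, takes its `top_n` genes (or all of its nonzero-score
#' genes when fewer than `top_n`, as happens for sparse boosters), tests
#' every gene set by [hypergeometric_enrichment()], adjusts p-values across
#' sets with Benjamini-Hochberg, keeps sets with `q <= q_threshold` sorted by
#' q then p, and displays the top 10.  Each displayed set is cross-flagged
#' with the other methods in whose top-100 significant sets it also appears.
#'
#' @param rankings named list of [gene_ranking()]s (one per method; for
#'   replicate-producing methods pass the first replicate).
#' @param collection a `gene_set_collection` from [read_gmt()].
#' @param universe background gene names; default: the gene universe of the
#'   first ranking (the post-filter gene list).
#' @param top_n list size (default 100).
#' @param q_threshold FDR cutoff (default 0.05).
#' @return an `ora_result`: list with `tables` (per-method data frame of all
#'   sets with `k`, `K`, `n`, `M`, `p`, `q`, `significant`), `top10`
#'   (per-method character vector, possibly empty) and `cross_flags`
#'   (per-method named list mapping displayed set -> flagging methods).
#' @export
ora_report <- function(rankings, collection, universe = NULL, top_n = 100L,
                       q_threshold = 0.05) {
  if (is.null(universe)) universe <- names(rankings[[1L]]$scores)
  tables <- lapply(rankings, function(rk) {
    n_use <- min(top_n, max(sum(rk$scores > 0), 1L), length(rk$scores))
    glist <- top_genes(rk, n_use)
    rows <- lapply(names(collection), function(nm) {
      h <- hypergeometric_enrichment(glist, collection[[nm]]$genes, universe)
      data.frame(set = nm, k = h$k, K = h$K, n = h$n, M = h$M, p = h$p,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- tab$q <= q_threshold
    tab[order(tab$q, tab$p, tab$set), ]
  })
  sig_sets <- lapply(tables, function(t) t$set[t$significant])
  top10 <- lapply(sig_sets, function(s) utils::head(s, 10L))
  top100 <- lapply(sig_sets, function(s) utils::head(s, 100L))
  cross_flags <- lapply(names(tables), function(m) {
    flags <- lapply(top10[[m]], function(set)
      names(tables)[vapply(names(tables), function(o)
        o != m && set %in% top100[[o]], logical(1))])
    stats::setNames(flags, top10[[m]])
  })
  names(cross_flags) <- names(tables)
  structure(list(tables = tables, top10 = top10, cross_flags = cross_flags,
                 top_n = top_n, q_threshold = q_threshold),
            class = "ora_result")
}
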