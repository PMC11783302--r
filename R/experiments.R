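#' Top-k overlap matrix across ranking methods
#'
#' For every method pair, the percentage of common genes among the top-k
#' lists, averaged over all replicate pairs; the lower triangle uses
#' `k_small`, the upper triangle `k_large`, and the diagonal holds the
#' within-method replicate overlap at `k_large` (100 by construction for
#' single-ranking methods).  Methods with fewer nonzero-score genes than `k`
#' are masked (`NA`) at that `k`, mirroring how sparse boosters that touch
#' only a few dozen genes cannot fill a top-100 list.
#'
#' @param rankings named list; each element is a list of [gene_ranking()]
#'   replicates for one method (a bare `gene_ranking` is promoted to a
#'   one-replicate list).
#' @param k_small lower-triangle list size (default 10).
#' @param k_large upper-triangle and diagonal list size (default 100).
#' @return an `overlap_matrix`: list with `matrix` (percentages), `k_small`,
#'   `k_large`, `replicate_counts`.
#' @export
overlap_matrix <- function(rankings, k_small = 10L, k_large = 100L) {
  if (length(rankings) < 2L) stop_config("need at least 2 methods")
  rankings <- lapply(rankings, function(r)
    if (inherits(r, "gene_ranking")) list(r) else r)
  universe <- sort(names(rankings[[1L]][[1L]]$scores))
  for (m in rankings) for (r in m)
    if (!identical(sort(names(r$scores)), universe))
      stop_format("rankings cover different gene universes")
  usable <- function(r, k) sum(r$scores > 0) >= k || length(universe) <= k
  pct_overlap <- function(ra, rb, k) {
    k <- min(k, length(universe))
    length(intersect(top_genes(ra, k), top_genes(rb, k))) / k * 100
  }
  cross_mean <- function(la, lb, k, within = FALSE) {
    if (!all(vapply(la, usable, logical(1), k)) ||
        !all(vapply(lb, usable, logical(1), k))) return(NA_real_)
    vals <- c()
    for (i in seq_along(la)) for (j in seq_along(lb)) {
      if (within && j <= i) next
      vals <- c(vals, pct_overlap(la[[i]], lb[[j]], k))
    }
    if (within && length(la) == 1L) 100 else mean(vals)
  }
  M <- length(rankings)
  out <- matrix(NA_real_, M, M, dimnames = list(names(rankings),
                                                names(rankings)))
  for (i in seq_len(M)) for (j in seq_len(M)) {
    out[i, j] <- if (i == j) cross_mean(rankings[[i]], rankings[[i]],
                                        k_large, within = TRUE)
    else if (i > j) cross_mean(rankings[[i]], rankings[[j]], k_small)
    else cross_mean(rankings[[i]], rankings[[j]], k_large)
  }
  structure(list(matrix = out, k_small = k_small, k_large = k_large,
                 replicate_counts = vapply(rankings, length, integer(1))),
            class = "overlap_matrix")
}

#' Experiment 0: aggregated prediction gaps without retraining
#'
#' For each (model, ranking) replicate pair, computes PGI and PGU over the
#' correctly classified training samples and aggregates to a per-replicate
#' mean, then across replicates to mean and standard deviation.  Also
#' reports `100 - 100*PGI`, the percentage of top-ranked genes that can be
#' masked before the model is disturbed.
#'
#' @param models list of trained models (one per replicate).
#' @param rankings list of [gene_ranking()]s matched to `models`.
#' @param pd a `processed_dataset`.
#' @param reference masking baseline; default [attribution_baseline()].
#' @param max_samples cap on the number of correctly classified training
#'   samples evaluated per replicate.
#' @param stride stride passed to [prediction_gap()].
#' @return list with per-replicate `pgi`, `pgu`, cross-replicate
#'   `pgi_mean/sd`, `pgu_mean/sd`, and `maskable_pct` (= 100 - 100*PGI mean).
#' @export
run_experiment_0 <- function(models, rankings, pd, reference = NULL,
                             max_samples = 25L, stride = 1L) {
  stopifnot(length(models) == length(rankings))
  if (is.null(reference)) reference <- attribution_baseline(pd)
  tr <- train_matrix(pd); ytr <- train_labels(pd)
  per_rep <- lapply(seq_along(models), function(r) {
    model <- models[[r]]; rk <- rankings[[r]]
    ok <- which(predict_class(model, tr) == ytr)
    if (!length(ok)) stop("no correctly classified training samples")
    ok <- ok[seq_len(min(length(ok), max_samples))]
    vals <- vapply(ok, function(i) {
      c(prediction_gap(model, tr[i, ], rk, "important_first", reference,
                       target_class = ytr[i], stride = stride)$pg_value,
        prediction_gap(model, tr[i, ], rk, "unimportant_first", reference,
                       target_class = ytr[i], stride = stride)$pg_value)
    }, numeric(2))
    c(pgi = mean(vals[1L, ]), pgu = mean(vals[2L, ]))
  })
  pgi <- vapply(per_rep, `[[`, numeric(1), "pgi")
  pgu <- vapply(per_rep, `[[`, numeric(1), "pgu")
  list(pgi = pgi, pgu = pgu,
       pgi_mean = mean(pgi), pgi_sd = stats::sd(pgi),
       pgu_mean = mean(pgu), pgu_sd = stats::sd(pgu),
       maskable_pct = 100 - 100 * mean(pgi))
}

subset_processed <- function(pd, genes) {
  keep <- match(genes, pd$kept_gene_names)
  out <- pd
  out$matrix <- pd$matrix[, keep, drop = FALSE]
  out$kept_gene_names <- pd$kept_gene_names[keep]
  out$standardizer_means <- pd$standardizer_means[keep]
  out$standardizer_stds <- pd$standardizer_stds[keep]
  out
}

#' Experiments 1 and 2: retraining on ranked gene subsets
#'
#' For each grid value `g`, retrains the model family from scratch on the
#' `g` highest-ranked (`selection = "top"`), lowest-ranked (`"bottom"`) or
#' randomly chosen (`"random"`) genes and evaluates balanced accuracy on the
#' held-out test samples.  Each ranking replicate is paired with one
#' retraining seed; for the GNN the co-expression graph is rebuilt on the
#' gene subset.
#'
#' @param pd a `processed_dataset`.
#' @param rankings a [gene_ranking()] or list of replicates.
#' @param model_family family name for [train_model()].
#' @param grid integer vector of gene counts (values capped at G).
#' @param selection `"top"`, `"bottom"` or `"random"`.
#' @param seeds integer retraining seeds, recycled to the replicate count.
#' @param ... extra arguments to [train_model()].
#' @return a `retrain_curve` data frame: `n_genes`, `accuracy_mean`,
#'   `accuracy_sd`, plus attributes `selection` and `method`.
#' @export
run_retrain_experiment <- function(pd, rankings, model_family,
                                   grid = c(1L, 5L, 10L, 50L, 100L, 500L,
                                            1000L),
                                   selection = c("top", "bottom", "random"),
                                   seeds = 1L, ...) {
  selection <- match.arg(selection)
  if (inherits(rankings, "gene_ranking")) rankings <- list(rankings)
  G <- ncol(pd$matrix)
  grid <- sort(unique(pmin(as.integer(grid), G)))
  if (model_family == "gnn") grid <- grid[grid >= 2L]
  seeds <- rep_len(as.integer(seeds), length(rankings))
  yte <- test_labels(pd)
  rows <- lapply(grid, function(g) {
    accs <- vapply(seq_along(rankings), function(r) {
      genes <- switch(selection,
        top = top_genes(rankings[[r]], g),
        bottom = top_genes(rankings[[r]], g, from = "bottom"),
        random = with_seed(seeds[r] + 7L * g,
                           sample(pd$kept_gene_names, g)))
      sub <- subset_processed(pd, genes)
      model <- train_model(model_family, sub, seed = seeds[r], ...)
      balanced_accuracy(predict_class(model, test_matrix(sub)), yte)
    }, numeric(1))
    c(mean(accs), stats::sd(accs))
  })
  out <- data.frame(n_genes = grid,
                    accuracy_mean = vapply(rows, `[`, numeric(1), 1L),
                    accuracy_sd = vapply(rows, `[`, numeric(1), 2L))
  attr(out, "selection") <- selection
  attr(out, "method") <- rankings[[1L]]$method
  class(out) <- c("retrain_curve", "data.frame")
  out
}

#' Spearman correlation of a ranking with the Welch t-statistic
#'
#' Correlates a ranking's scores with `|t|` from a Welch differential-
#' expression analysis over the same genes, and compares the `|t|`
#' distribution of the ranking's top 100 genes against 100 random genes —
#' the diagnostic separating statistically driven rankings from ones that
#' ignore expression differences.
#'
#' @param ranking a [gene_ranking()].
#' @param de_stats the `stats` data frame from
#'   [rank_differential_expression()].
#' @param top_k list size for the top-vs-random comparison.
#' @param seed seed for the random gene draw.
#' @return list with `rho` (Spearman), `top_mean_abs_t`, `random_mean_abs_t`.
#' @export
tstat_correlation <- function(ranking, de_stats, top_k = 100L, seed = 1L) {
  idx <- match(names(ranking$scores), de_stats$gene_name)
  if (anyNA(idx)) stop_format("ranking and t-statistics cover different genes")
  abs_t <- abs(de_stats$t[idx])
  if (stats::sd(ranking$scores) == 0 || stats::sd(abs_t) == 0)
    stop("constant scores: Spearman correlation undefined")
  rho <- stats::cor(ranking$scores, abs_t, method = "spearman")
  top <- top_genes(ranking, top_k)
  rnd <- with_seed(seed, sample(names(ranking$scores), min(top_k,
                                length(ranking$scores))))
  list(rho = rho,
       top_mean_abs_t = mean(abs_t[match(top, names(ranking$scores))]),
       random_mean_abs_t = mean(abs_t[match(rnd, names(ranking$scores))]))
}
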