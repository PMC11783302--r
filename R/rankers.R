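#' Rank genes by variance
#'
#' Population variance (`1/N` convention) of each gene across samples; a
#' class-agnostic filter statistic.
#'
#' @param matrix numeric matrix, samples x genes, with gene column names.
#' @return a [gene_ranking()] with method `"var"`.
#' @export
rank_variance <- function(matrix) {
  if (nrow(matrix) < 2L) stop_config("need at least 2 samples")
  mu <- colMeans(matrix)
  v <- colMeans(sweep(matrix, 2L, mu)^2)
  gene_ranking(v, "var")
}

#' Rank genes by their loading on the first principal component
#'
#' Scores are `|v1_g|`, the absolute coefficients of the unit leading
#' eigenvector of the gene-gene covariance of the centred matrix; the sign
#' indeterminacy of eigenvectors is irrelevant under the absolute value.
#'
#' @param matrix numeric matrix, samples x genes.
#' @return a [gene_ranking()] with method `"pca"`.
#' @export
rank_pca <- function(matrix) {
  if (nrow(matrix) < 2L) stop_config("need at least 2 samples")
  Xc <- sweep(matrix, 2L, colMeans(matrix))
  sv <- svd(Xc, nu = 0L, nv = 2L)
  if (length(sv$d) > 1L && sv$d[1L] > 0 &&
      (sv$d[1L] - sv$d[2L]) / sv$d[1L] < 1e-8)
    warning("leading eigenvalue is (near-)degenerate; PCA ranking unstable")
  v1 <- sv$v[, 1L]
  gene_ranking(stats::setNames(abs(v1), colnames(matrix)), "pca")
}

# Mutual information between one continuous variable and a discrete label by
# the nearest-neighbour estimator of Ross (2014): for each point, take the
# distance to its k-th neighbour within its own class, count how many points
# of the full sample fall strictly inside that radius, and combine the counts
# through digamma terms.
mi_knn_1d <- function(x, y, k) {
  N <- length(x)
  xs <- sort(x)
  d_k <- numeric(N)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    v <- x[idx]
    D <- abs(outer(v, v, "-"))
    d_k[idx] <- apply(D, 1L, function(r) sort.int(r, partial = k + 1L)[k + 1L])
  }
  # count of points strictly inside the radius, the point itself included
  # (the convention of the k-NN estimator for continuous x, discrete y)
  hi <- findInterval(x + d_k, xs, left.open = TRUE)   # values < x + d
  lo <- findInterval(x - d_k, xs)                     # values <= x - d
  m_i <- pmax(hi - lo, 1L)
  n_y <- tabulate(y)[y]
  max(digamma(N) - mean(digamma(n_y)) + digamma(k) - mean(digamma(m_i)), 0)
}

#' Rank genes by mutual information with the class label
#'
#' Per-gene MI `I(X_g; Y)` between continuous expression and the discrete
#' class, estimated with a k-nearest-neighbour estimator (negative estimates
#' are clipped to zero).  Scores are in nats.
#'
#' @param matrix numeric matrix, samples x genes.
#' @param labels integer class labels.
#' @param neighbors `k` of the estimator (default 3).
#' @return a [gene_ranking()] with method `"mi"`.
#' @export
rank_mutual_information <- function(matrix, labels, neighbors = 3L) {
  if (length(unique(labels)) < 2L) stop_config("need at least 2 classes")
  if (any(tabulate(labels) < neighbors + 1L))
    stop_config("every class needs more than `neighbors` samples")
  # tiny fixed-seed jitter breaks ties (log-CPM zeros) without perturbing
  # the estimate
  jit <- with_seed(190741L, matrix(stats::rnorm(length(matrix)), nrow(matrix)))
  scores <- vapply(seq_len(ncol(matrix)), function(g) {
    x <- matrix[, g]
    x <- x + jit[, g] * (1e-9 * (stats::sd(x) + 1e-12))
    mi_knn_1d(x, labels, neighbors)
  }, numeric(1))
  gene_ranking(stats::setNames(scores, colnames(matrix)), "mi")
}

#' Welch-t differential-expression ranking
#'
#' Per gene, a Welch unequal-variance two-sample t-test between classes on
#' the supplied (log-CPM) values.  With more than two classes every unordered
#' class pair is tested and the minimal raw p-value per gene is kept, then
#' Benjamini-Hochberg adjusted across genes.  Scores are
#' `-log10(adjusted p)`.  Genes with zero variance in both classes of every
#' pair get p = 1 with a warning.  Externally computed DESeq2/edgeR tables
#' can be imported through [read_ranking()] on the same score scale.
#'
#' @param matrix numeric matrix of normalized expression, samples x genes.
#' @param labels integer class labels.
#' @return list with `ranking` (a [gene_ranking()], method `"de"`) and
#'   `stats`, a data frame holding per-gene `t` (the pair-minimal Welch
#'   statistic), `p_raw`, `p_adjusted` and `class_pair_used`.
#' @export
rank_differential_expression <- function(matrix, labels) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_config("need at least 2 classes")
  if (any(tabulate(labels) < 2L)) stop_config("every class needs >= 2 samples")
  G <- ncol(matrix)
  mus <- lapply(classes, function(cl) colMeans(matrix[labels == cl, , drop = FALSE]))
  vars <- lapply(classes, function(cl)
    apply(matrix[labels == cl, , drop = FALSE], 2L, stats::var))
  ns <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  pairs <- utils::combn(seq_along(classes), 2L)
  p_min <- rep(Inf, G); t_at_min <- rep(0, G)
  pair_used <- rep(NA_character_, G)
  for (pi in seq_len(ncol(pairs))) {
    a <- pairs[1L, pi]; b <- pairs[2L, pi]
    se2 <- vars[[a]] / ns[a] + vars[[b]] / ns[b]
    tt <- (mus[[a]] - mus[[b]]) / sqrt(se2)
    df <- se2^2 / ((vars[[a]] / ns[a])^2 / (ns[a] - 1) +
                     (vars[[b]] / ns[b])^2 / (ns[b] - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    degenerate <- !is.finite(tt)
    if (any(degenerate)) {
      p[degenerate] <- 1
      tt[degenerate] <- 0
    }
    upd <- p < p_min
    p_min[upd] <- p[upd]
    t_at_min[upd] <- tt[upd]
    pair_used[upd] <- sprintf("(%d,%d)", classes[a], classes[b])
  }
  if (any(p_min == 1 & t_at_min == 0))
    warning("gene(s) with zero variance in both classes; p set to 1")
  p_adj <- stats::p.adjust(p_min, method = "BH")
  scores <- -log10(pmax(p_adj, .Machine$double.xmin))
  names(scores) <- colnames(matrix)
  stats_df <- data.frame(gene_name = colnames(matrix), t = t_at_min,
                         p_raw = p_min, p_adjusted = p_adj,
                         class_pair_used = pair_used,
                         stringsAsFactors = FALSE)
  list(ranking = gene_ranking(scores, "de"), stats = stats_df)
}

#' Rank genes by logistic-regression coefficient magnitudes
#'
#' Binary tasks score each gene by `|W_g|`; multi-class tasks by the mean of
#' `|W_cg|` over classes.
#'
#' @param model an `lr_model` from [train_logistic()].
#' @return a [gene_ranking()] with method `"lr_weight"`.
#' @export
rank_lr_weights <- function(model) {
  if (!inherits(model, "lr_model"))
    stop_config("lr-weight ranking requires a logistic-regression model")
  W <- model$W
  scores <- if (model$n_classes == 2L) abs(W[2L, ]) else colMeans(abs(W))
  gene_ranking(stats::setNames(scores, model$gene_names), "lr_weight",
               replicate = model$replicate_seed)
}

#' Rank genes by boosted-tree split gain
#'
#' Total gain of each gene across all splits; genes never used by a tree
#' score exactly 0.  The count of nonzero-gain genes is attached as attribute
#' `n_used` (sparse boosters typically touch only a few dozen genes).
#'
#' @param model a `gbt_model` from [train_gbt()].
#' @return a [gene_ranking()] with method `"gbt_gain"`.
#' @export
rank_gbt_gain <- function(model) {
  if (!inherits(model, "gbt_model"))
    stop_config("gain ranking requires a boosted-tree model")
  r <- gene_ranking(model$feature_importances, "gbt_gain",
                    replicate = model$replicate_seed)
  attr(r, "n_used") <- sum(model$feature_importances > 0)
  r
}
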