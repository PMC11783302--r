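#' Configuration for the RNA-seq count simulator
#'
#' Describes a synthetic bulk expression study: per-class sample counts
#' (imbalance is expressed directly, as in real tumour/normal cohorts), a
#' negative-binomial noise model, planted differentially expressed (DE) genes
#' with a fixed log2 fold change, and optional redundant gene blocks driven by
#' a shared latent factor.
#'
#' @param n_samples_per_class positive integer vector, one entry per class.
#' @param n_genes total number of genes.
#' @param n_de_genes_per_class number of genes up-regulated in each class
#'   (disjoint across classes).
#' @param log2_fold_change log2 fold change applied to a planted gene's mean
#'   in its class; 0 gives a null dataset.
#' @param nb_dispersion negative-binomial dispersion, so that
#'   `variance = mu + mu^2 * dispersion`.
#' @param baseline_mean_log_range length-2 numeric: per-gene baseline means
#'   are `2^u` with `u` uniform in this range (log2 scale), covering low- and
#'   high-expression regimes.
#' @param n_redundant_blocks number of correlated gene blocks.
#' @param block_size genes per block.
#' @param block_correlation target pairwise Pearson correlation of counts
#'   within a block, in `[0, 1)`; realized through a shared standard-normal
#'   latent factor whose loading is solved from the negative-binomial
#'   moment equations.
#' @param block_log2_fc optional class signal carried by the blocks: each
#'   block is assigned a class (round-robin) and its genes gain this log2
#'   shift in that class.  Default 0 (blocks are pure redundancy).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples_per_class = c(100L, 100L),
                             n_genes = 1000L,
                             n_de_genes_per_class = 20L,
                             log2_fold_change = 2,
                             nb_dispersion = 0.05,
                             baseline_mean_log_range = c(0, 10),
                             n_redundant_blocks = 0L,
                             block_size = 10L,
                             block_correlation = 0.8,
                             block_log2_fc = 0,
                             seed = 1L) {
  cfg <- list(n_samples_per_class = as.integer(n_samples_per_class),
              n_genes = as.integer(n_genes),
              n_de_genes_per_class = as.integer(n_de_genes_per_class),
              log2_fold_change = log2_fold_change,
              nb_dispersion = nb_dispersion,
              baseline_mean_log_range = baseline_mean_log_range,
              n_redundant_blocks = as.integer(n_redundant_blocks),
              block_size = as.integer(block_size),
              block_correlation = block_correlation,
              block_log2_fc = block_log2_fc,
              seed = as.integer(seed))
  n_classes <- length(cfg$n_samples_per_class)
  if (n_classes < 1L || any(cfg$n_samples_per_class < 1L))
    stop_config("need at least one sample in every class")
  if (cfg$n_genes < 1L) stop_config("n_genes must be positive")
  if (cfg$n_de_genes_per_class < 0L || cfg$log2_fold_change < 0)
    stop_config("effect parameters must be nonnegative")
  if (cfg$nb_dispersion <= 0) stop_config("nb_dispersion must be > 0")
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1)
    stop_config("block_correlation must lie in [0, 1)")
  if (cfg$n_redundant_blocks > 0L && cfg$block_size < 2L)
    stop_config("block_size must be >= 2")
  planted <- cfg$n_de_genes_per_class * n_classes +
    cfg$n_redundant_blocks * cfg$block_size
  if (planted > cfg$n_genes)
    stop_config("planted DE genes plus redundant blocks (", planted,
                ") exceed n_genes (", cfg$n_genes, ")")
  structure(cfg, class = "synthetic_config")
}

# Latent-factor loading achieving a target within-block count correlation.
# With mean mu_n = mu * exp(a z), z ~ N(0,1), and NB(mu_n, dispersion phi):
#   E[X]  = mu m1,  m1 = exp(a^2/2),  m2 = exp(2 a^2)
#   Var X = mu m1 + mu^2 ((1 + phi) m2 - m1^2)
#   Cov   = mu^2 (m2 - m1^2)
# The correlation is increasing in a and bounded by ~1/(1+phi); a target
# beyond that bound is infeasible for the given dispersion.
block_loading <- function(rho, mu, phi) {
  if (rho == 0) return(0)
  f <- function(a) {
    m1 <- exp(a^2 / 2); m2 <- exp(2 * a^2)
    mu^2 * (m2 - m1^2) /
      (mu * m1 + mu^2 * ((1 + phi) * m2 - m1^2)) - rho
  }
  if (f(3) < 0)
    stop_config("block_correlation ", rho, " is unreachable at dispersion ",
                phi, "; lower the correlation or the dispersion")
  stats::uniroot(f, c(1e-9, 3), tol = 1e-10)$root
}

#' Simulate a count matrix with planted class structure
#'
#' Draws nonnegative-integer counts from a negative-binomial model
#' (`variance = mu + mu^2 * dispersion`).  Genes planted as DE for class `c`
#' have their mean multiplied by `2^log2_fold_change` in that class.  Genes in
#' a redundant block share a standard-normal latent factor added on the
#' log-mean scale, with loading solved so the pairwise count correlation
#' matches `block_correlation`; block baseline means are drawn from the upper
#' half of `baseline_mean_log_range` so the latent signal is not drowned in
#' shot noise.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth` (a
#'   `planted_truth`: `de_gene_indices_by_class`, `redundant_block_membership`,
#'   `block_class`, `true_log2_fold_changes`, `gene_names`, `block_loading`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    C <- length(config$n_samples_per_class)
    G <- config$n_genes
    N <- sum(config$n_samples_per_class)
    labels <- rep(seq_len(C), config$n_samples_per_class)
    gene_names <- sprintf("G%06d", seq_len(G))

    lo <- config$baseline_mean_log_range[1]
    hi <- config$baseline_mean_log_range[2]
    base_log2 <- stats::runif(G, lo, hi)

    # disjoint planted structure: DE genes per class, then blocks
    n_planted_de <- config$n_de_genes_per_class * C
    n_block_genes <- config$n_redundant_blocks * config$block_size
    planted_idx <- sample.int(G, n_planted_de + n_block_genes)
    de_by_class <- vector("list", C)
    pos <- 0L
    for (cl in seq_len(C)) {
      de_by_class[[cl]] <- sort(planted_idx[pos + seq_len(config$n_de_genes_per_class)])
      pos <- pos + config$n_de_genes_per_class
    }
    block_membership <- rep(NA_integer_, G)
    block_class <- integer(0)
    if (config$n_redundant_blocks > 0L) {
      block_class <- rep_len(seq_len(C), config$n_redundant_blocks)
      for (b in seq_len(config$n_redundant_blocks)) {
        gidx <- planted_idx[pos + seq_len(config$block_size)]
        pos <- pos + config$block_size
        block_membership[gidx] <- b
        # common baseline, upper half of the range: keeps shot noise small
        base_log2[gidx] <- stats::runif(1, (lo + hi) / 2, hi)
      }
    }

    lfc <- rep(0, G)
    for (cl in seq_len(C)) lfc[de_by_class[[cl]]] <- config$log2_fold_change
    in_block <- which(!is.na(block_membership))
    if (config$block_log2_fc > 0) lfc[in_block] <- config$block_log2_fc

    # per-sample log2 mean matrix, built class-block by class-block
    log2_mu <- matrix(rep(base_log2, each = N), nrow = N)
    for (cl in seq_len(C)) {
      rows <- which(labels == cl)
      log2_mu[rows, de_by_class[[cl]]] <-
        log2_mu[rows, de_by_class[[cl]]] + config$log2_fold_change
    }
    loading <- 0
    if (config$n_redundant_blocks > 0L) {
      mu_block <- 2^((lo + hi) * 3 / 4)  # representative block mean
      loading <- block_loading(config$block_correlation, mu_block,
                               config$nb_dispersion)
      for (b in seq_len(config$n_redundant_blocks)) {
        gidx <- which(block_membership == b)
        z <- stats::rnorm(N)
        log2_mu[, gidx] <- log2_mu[, gidx] + loading * z / log(2)
        if (config$block_log2_fc > 0) {
          rows <- which(labels == block_class[b])
          log2_mu[rows, gidx] <- log2_mu[rows, gidx] + config$block_log2_fc
        }
      }
    }

    counts <- matrix(stats::rnbinom(N * G, mu = 2^log2_mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = N, ncol = G,
                     dimnames = list(sprintf("S%05d", seq_len(N)), gene_names))
    truth <- structure(list(de_gene_indices_by_class = de_by_class,
                            redundant_block_membership = block_membership,
                            block_class = block_class,
                            true_log2_fold_changes = lfc,
                            gene_names = gene_names,
                            block_loading = loading),
                       class = "planted_truth")
    list(dataset = expression_dataset(counts, labels, C), truth = truth)
  })
}

#' Build a toy GMT collection from planted truth
#'
#' One gene set per class holding that class's planted DE genes padded with
#' random non-planted genes, plus `n_decoy_sets` sets of random genes.  Used
#' to exercise over-representation analysis with a known answer.
#'
#' @param truth a `planted_truth` from [generate_counts()].
#' @param n_decoy_sets number of random decoy sets.
#' @param seed integer seed.
#' @param pad random genes appended to each class set.
#' @return a `gene_set_collection`.
#' @export
generate_toy_gmt <- function(truth, n_decoy_sets = 10L, seed = 1L, pad = 5L) {
  stopifnot(inherits(truth, "planted_truth"))
  de_all <- unlist(truth$de_gene_indices_by_class)
  if (length(de_all) == 0L) stop_config("truth has no planted DE genes")
  G <- length(truth$gene_names)
  with_seed(seed, {
    sets <- list()
    pool <- setdiff(seq_len(G), de_all)
    for (cl in seq_along(truth$de_gene_indices_by_class)) {
      idx <- truth$de_gene_indices_by_class[[cl]]
      if (length(idx) == 0L) next
      extra <- sample(pool, min(pad, length(pool)))
      sets[[sprintf("CLASS%d_UP", cl)]] <-
        list(description = sprintf("planted DE genes of class %d", cl),
             genes = truth$gene_names[c(idx, extra)])
      size <- length(idx) + length(extra)
    }
    if (n_decoy_sets > 0L) {
      for (d in seq_len(n_decoy_sets)) {
        sets[[sprintf("DECOY%03d", d)]] <-
          list(description = "random gene set",
               genes = truth$gene_names[sample.int(G, size)])
      }
    }
    structure(sets, class = "gene_set_collection")
  })
}
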