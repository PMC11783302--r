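#' Filter genes before normalization
#'
#' Removes, in order: (i) genes with any `NaN`/`NA` value; (ii) genes whose
#' maximal count across the dataset is 0; (iii) low-expressed genes for which,
#' in every class, strictly more than `sample_fraction` of that class's
#' samples have counts below `count_threshold`.  Under the default quantifier
#' (`quantifier = "every"`) a gene expressed in a single class — a plausible
#' marker — is kept; `quantifier = "any"` applies the stricter reading where
#' one low-count class suffices for removal.
#'
#' @param data an [expression_dataset()].
#' @param count_threshold low-count threshold (default 5).
#' @param sample_fraction fraction of samples that must be below the
#'   threshold (default 0.75).
#' @param quantifier `"every"` or `"any"` class (see above).
#' @return the filtered [expression_dataset()]; removal counts per rule are
#'   attached as attribute `removed`.
#' @export
filter_genes <- function(data, count_threshold = 5, sample_fraction = 0.75,
                         quantifier = c("every", "any")) {
  quantifier <- match.arg(quantifier)
  counts <- data$counts
  nan_gene <- apply(counts, 2L, anyNA)
  zero_gene <- !nan_gene & apply(counts, 2L, max) == 0
  low_by_class <- vapply(seq_len(data$n_classes), function(cl) {
    sub <- counts[data$labels == cl, , drop = FALSE]
    colMeans(sub < count_threshold) > sample_fraction
  }, logical(ncol(counts)))
  low_by_class <- matrix(low_by_class, ncol = data$n_classes)
  low_gene <- if (quantifier == "every") apply(low_by_class, 1L, all)
              else apply(low_by_class, 1L, any)
  low_gene <- low_gene & !nan_gene & !zero_gene
  keep <- !(nan_gene | zero_gene | low_gene)
  if (!any(keep)) stop_format("all genes removed by filtering")
  out <- expression_dataset(counts[, keep, drop = FALSE], data$labels,
                            data$n_classes)
  attr(out, "removed") <- c(nan = sum(nan_gene), all_zero = sum(zero_gene),
                            low_count = sum(low_gene))
  out
}

#' Library-size normalization: log2 counts per million
#'
#' Per sample, `value = log2(1 + count * 1e6 / total)`.  The pseudocount of 1
#' keeps zero counts finite.  Scaling all of a sample's counts by a constant
#' leaves its normalized values unchanged.
#'
#' @param data an [expression_dataset()].
#' @return the dataset with `counts` replaced by log2-CPM values.
#' @export
normalize_cpm <- function(data) {
  totals <- rowSums(data$counts)
  if (any(totals <= 0))
    stop_format("sample(s) with zero total count: ",
                paste(data$sample_ids[totals <= 0], collapse = ", "))
  logcpm <- log2(1 + data$counts * (1e6 / totals))
  out <- data
  out$counts <- logcpm
  out
}

#' Stratified train/test split
#'
#' Per class, `round(fraction * class size)` samples (round half up) go to
#' training, adjusted by at most one sample per class to hit the global
#' target `round(fraction * N)`; every class keeps at least one training and
#' one test sample.  Deterministic under `seed`.
#'
#' @param data an [expression_dataset()].
#' @param train_fraction fraction of samples used for training (default 0.6).
#' @param seed integer seed.
#' @return list with integer vectors `train_index` and `test_index`.
#' @export
split_samples <- function(data, train_fraction = 0.6, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must lie strictly between 0 and 1")
  sizes <- tabulate(data$labels, data$n_classes)
  if (any(sizes < 2L))
    stop_config("class with a single sample cannot be split")
  half_up <- function(x) floor(x + 0.5)
  n_tr <- pmin(pmax(half_up(train_fraction * sizes), 1L), sizes - 1L)
  target <- half_up(train_fraction * sum(sizes))
  # nudge the largest-slack classes by +/-1 toward the global target
  while (sum(n_tr) < target && any(adjust <- n_tr < sizes - 1L)) {
    i <- which(adjust)[which.max(sizes[adjust])]
    n_tr[i] <- n_tr[i] + 1L
  }
  while (sum(n_tr) > target && any(adjust <- n_tr > 1L)) {
    i <- which(adjust)[which.max(sizes[adjust])]
    n_tr[i] <- n_tr[i] - 1L
  }
  with_seed(seed, {
    train <- unlist(lapply(seq_len(data$n_classes), function(cl) {
      idx <- which(data$labels == cl)
      sample(idx, n_tr[cl])
    }))
    train <- sort(train)
    list(train_index = train,
         test_index = setdiff(seq_along(data$labels), train))
  })
}

#' Standardize using training-set statistics only
#'
#' Columns are z-scored with means and standard deviations computed from the
#' training rows and applied to all samples; standard deviations use the
#' population (1/N) convention, and values below 1e-12 are replaced by 1 with
#' a warning.
#'
#' @param data an [expression_dataset()] holding log-CPM values.
#' @param train_index training sample indices (from [split_samples()]).
#' @param test_index test sample indices.
#' @return a `processed_dataset`: `matrix` (standardized, all samples),
#'   `kept_gene_names`, `train_index`, `test_index`, `standardizer_means`,
#'   `standardizer_stds`, `labels`, `n_classes`.
#' @export
standardize <- function(data, train_index, test_index) {
  m <- data$counts
  mu <- colMeans(m[train_index, , drop = FALSE])
  sd_ <- sqrt(colMeans(sweep(m[train_index, , drop = FALSE], 2L, mu)^2))
  if (any(bad <- sd_ < 1e-12)) {
    warning(sum(bad), " gene(s) with ~zero training variance; std set to 1")
    sd_[bad] <- 1
  }
  z <- sweep(sweep(m, 2L, mu), 2L, sd_, "/")
  structure(list(matrix = z, kept_gene_names = colnames(m),
                 train_index = train_index, test_index = test_index,
                 standardizer_means = mu, standardizer_stds = sd_,
                 labels = data$labels, n_classes = data$n_classes),
            class = "processed_dataset")
}

#' @exportS3Method base::print
print.processed_dataset <- function(x, ...) {
  cat(sprintf("<processed_dataset> %d samples (%d train / %d test) x %d genes, %d classes\n",
              nrow(x$matrix), length(x$train_index), length(x$test_index),
              ncol(x$matrix), x$n_classes))
  invisible(x)
}

#' Full preprocessing chain
#'
#' [filter_genes()] then [normalize_cpm()] then [split_samples()] then
#' [standardize()], with the defaults used throughout the package.
#'
#' @inheritParams filter_genes
#' @inheritParams split_samples
#' @return a `processed_dataset`.
#' @export
preprocess <- function(data, train_fraction = 0.6, seed = 1L,
                       count_threshold = 5, sample_fraction = 0.75,
                       quantifier = "every") {
  f <- filter_genes(data, count_threshold, sample_fraction, quantifier)
  n <- normalize_cpm(f)
  sp <- split_samples(n, train_fraction, seed)
  standardize(n, sp$train_index, sp$test_index)
}

# Training / test views used by the model code.
train_matrix <- function(pd) pd$matrix[pd$train_index, , drop = FALSE]
test_matrix <- function(pd) pd$matrix[pd$test_index, , drop = FALSE]
train_labels <- function(pd) pd$labels[pd$train_index]
test_labels <- function(pd) pd$labels[pd$test_index]
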