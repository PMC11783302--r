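#' Integrated-gradients attribution for one sample
#'
#' Attributes the class-probability output of a gradient-based model to each
#' gene: `phi_g = (x_g - x'_g) * integral over alpha of d f_c / d x_g` along
#' the straight path from the baseline `x'` to the sample `x`, approximated
#' with a midpoint Riemann sum.  Satisfies completeness up to the integration
#' residual: the scores sum to `f_c(x) - f_c(x')`.
#'
#' @param model a trained `lr_model`, `mlp_model` or `gnn_model` (boosted
#'   trees expose no gradients and are rejected).
#' @param sample numeric vector of length G (standardized scale).
#' @param baseline numeric vector of length G, the reference sample.
#' @param target_class class index whose probability is attributed.
#' @param n_steps number of midpoint integration steps (default 128).
#' @return numeric vector of per-gene scores named by gene, with attributes
#'   `completeness_residual` and `delta_f` (`f_c(x) - f_c(x')`).
#' @export
integrated_gradients <- function(model, sample, baseline, target_class,
                                 n_steps = 128L) {
  if (inherits(model, "gbt_model"))
    stop("integrated gradients require a gradient-based model (lr, mlp, gnn)")
  if (length(sample) != length(baseline))
    stop_config("sample and baseline dimensions differ")
  diff <- sample - baseline
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  Z <- outer(alphas, diff) + rep(baseline, each = n_steps)
  Gm <- input_gradient(model, Z, target_class)
  phi <- diff * colMeans(Gm)
  names(phi) <- model$gene_names
  ends <- predict_proba(model, rbind(baseline, sample))[, target_class]
  delta <- ends[2L] - ends[1L]
  attr(phi, "delta_f") <- delta
  attr(phi, "completeness_residual") <- abs(sum(phi) - delta)
  phi
}

#' Per-class aggregation of local attributions
#'
#' Each correctly classified training sample's local score vector is taken in
#' absolute value, normalized to unit Euclidean norm, and the normalized
#' vectors are averaged within the class.  Samples with an all-zero
#' attribution vector are dropped with a warning (their norm is undefined).
#'
#' @param local_list list of local score vectors (one per sample of the
#'   class, e.g. from [integrated_gradients()]).
#' @return numeric vector of nonnegative per-gene class scores.
#' @export
aggregate_class_scores <- function(local_list) {
  norms <- vapply(local_list, function(v) sqrt(sum(v^2)), numeric(1))
  if (any(norms == 0)) {
    warning(sum(norms == 0), " sample(s) with all-zero attributions dropped")
    local_list <- local_list[norms > 0]
    norms <- norms[norms > 0]
  }
  if (length(local_list) == 0L)
    stop("no usable samples for class aggregation")
  acc <- Reduce(`+`, Map(function(v, nr) abs(v) / nr, local_list, norms))
  acc / length(local_list)
}

#' Global attribution score across classes
#'
#' Mean of the per-class score vectors; with a single class vector (the
#' binary tumour-class convention) it is the identity.
#'
#' @param class_scores list of per-class score vectors of equal length.
#' @return numeric per-gene vector.
#' @export
aggregate_global <- function(class_scores) {
  if (!length(class_scores)) stop_config("no class score vectors supplied")
  len <- vapply(class_scores, length, integer(1))
  if (length(unique(len)) != 1L) stop_config("class vectors differ in length")
  Reduce(`+`, class_scores) / length(class_scores)
}

#' Baseline sample for attributions and masking
#'
#' Binary convention: mean of the training samples of the `normal_class`
#' (class 1 by default).  Multi-class convention: mean of all training
#' samples.
#'
#' @param pd a `processed_dataset`.
#' @param normal_class class whose training mean serves as baseline in the
#'   binary case.
#' @return numeric vector of length G.
#' @export
attribution_baseline <- function(pd, normal_class = 1L) {
  tr <- train_matrix(pd)
  if (pd$n_classes == 2L)
    colMeans(tr[train_labels(pd) == normal_class, , drop = FALSE])
  else colMeans(tr)
}

#' Integrated-gradients gene ranking for one model replicate
#'
#' Computes local attributions on correctly classified training samples,
#' aggregates them per class, and averages across the studied classes.
#' For binary tasks only the `target_classes` (default: class 2, the
#' "tumour" class in the simulator's convention) are attributed against the
#' normal-class mean baseline; multi-class tasks attribute every class
#' against the global training mean.
#'
#' @param model a gradient-based trained model.
#' @param pd a `processed_dataset`.
#' @param n_steps integration steps.
#' @param target_classes classes to attribute; default class 2 for binary
#'   tasks, all classes otherwise.
#' @param baseline optional baseline override.
#' @param max_samples_per_class cap on attributed samples per class (they are
#'   the first correctly classified training samples, for reproducibility).
#' @return a [gene_ranking()] with method `"ig"`, carrying the per-class
#'   score vectors as attribute `class_scores`.
#' @export
rank_integrated_gradients <- function(model, pd, n_steps = 128L,
                                      target_classes = NULL, baseline = NULL,
                                      max_samples_per_class = Inf) {
  if (is.null(target_classes))
    target_classes <- if (pd$n_classes == 2L) 2L else seq_len(pd$n_classes)
  if (is.null(baseline)) baseline <- attribution_baseline(pd)
  tr <- train_matrix(pd); ytr <- train_labels(pd)
  pred <- predict_class(model, tr)
  class_scores <- lapply(target_classes, function(cl) {
    idx <- which(ytr == cl & pred == cl)
    if (!length(idx))
      stop("no correctly classified training sample in class ", cl)
    idx <- idx[seq_len(min(length(idx), max_samples_per_class))]
    locals <- lapply(idx, function(i)
      integrated_gradients(model, tr[i, ], baseline, cl, n_steps))
    aggregate_class_scores(locals)
  })
  scores <- aggregate_global(class_scores)
  names(scores) <- pd$kept_gene_names
  r <- gene_ranking(scores, "ig", replicate = model$replicate_seed)
  attr(r, "class_scores") <- class_scores
  r
}

#' Prediction-gap curve under progressive masking
#'
#' Masks genes one by one, in the order implied by a ranking, by substituting
#' the reference value for the sample value, and records the model's output
#' probability for the sample's class after each step.  The prediction gap is
#' `PG = (1/G) * sum_m max(f_c(x) - f_c(x_m), 0) / f_c(x)`.  Masking in
#' descending importance gives PGI, ascending gives PGU, and `"random"` uses
#' a seeded permutation.
#'
#' @param model a trained model.
#' @param sample numeric vector (standardized scale).
#' @param ranking a [gene_ranking()] over the model's genes.
#' @param order `"important_first"`, `"unimportant_first"` or `"random"`.
#' @param reference baseline vector used for masking.
#' @param target_class class whose probability is tracked; defaults to the
#'   model's predicted class for the sample.
#' @param stride evaluate every `stride`-th mask size (with the final full
#'   mask always included); the scalar is then computed on the strided grid.
#' @param seed seed for the `"random"` order.
#' @return a `pg_curve`: list with `masked_counts`, `outputs` (`f_c` after
#'   each mask size, starting at m = 0), `pg_value`, `order`, `target_class`.
#' @export
prediction_gap <- function(model, sample, ranking,
                           order = c("important_first", "unimportant_first",
                                     "random"),
                           reference, target_class = NULL, stride = 1L,
                           seed = 1L) {
  order <- match.arg(order)
  G <- length(sample)
  stopifnot(length(reference) == G, length(ranking$ranks) == G)
  if (is.null(target_class))
    target_class <- predict_class(model, matrix(sample, 1L))
  f0 <- predict_proba(model, matrix(sample, 1L))[, target_class]
  if (f0 == 0) stop("f_c(x) is zero; prediction gap undefined")
  gene_order <- switch(order,
    important_first = order(ranking$ranks),
    unimportant_first = order(-ranking$ranks),
    random = with_seed(seed, sample.int(G)))
  ms <- unique(c(seq(0L, G, by = stride), G))
  Xm <- matrix(sample, length(ms), G, byrow = TRUE)
  for (k in seq_along(ms)) {
    if (ms[k] > 0L) {
      idx <- gene_order[seq_len(ms[k])]
      Xm[k, idx] <- reference[idx]
    }
  }
  outs <- predict_proba(model, Xm)[, target_class]
  gaps <- pmax(f0 - outs[-1L], 0) / f0
  pg <- mean(gaps)
  structure(list(masked_counts = ms, outputs = outs, pg_value = pg,
                 order = order, target_class = target_class, f0 = f0),
            class = "pg_curve")
}
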