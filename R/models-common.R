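#' Class-probability predictions
#'
#' Every trained model returns an `n x C` matrix of class probabilities whose
#' rows sum to 1 (binary sigmoid models are presented as two-column softmax).
#'
#' @param model a trained model (`lr_model`, `mlp_model`, `gnn_model`,
#'   `gbt_model`).
#' @param X numeric matrix, samples x genes, on the standardized scale used
#'   for training.
#' @return matrix of probabilities, `n x n_classes`.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

#' Gradient of a class probability with respect to the input genes
#'
#' Defined for the gradient-based families (logistic regression, MLP, GNN);
#' boosted trees have no input gradient.
#'
#' @param model a trained model.
#' @param X numeric matrix, samples x genes.
#' @param class target class index (probability output differentiated).
#' @return matrix `n x G` of gradients `d f_class / d x`.
#' @export
input_gradient <- function(model, X, class) UseMethod("input_gradient")

#' @export
input_gradient.default <- function(model, X, class)
  stop("input gradients are not defined for model family '",
       class(model)[1], "'")

#' Predicted class labels
#' @inheritParams predict_proba
#' @return integer vector of class indices.
#' @export
predict_class <- function(model, X) max.col(predict_proba(model, X),
                                            ties.method = "first")

#' Balanced accuracy
#'
#' Mean over classes of the per-class recall; insensitive to class imbalance.
#'
#' @param predicted integer vector of predicted classes.
#' @param truth integer vector of true classes; every class in
#'   `1..max(truth)` must be present.
#' @return a number in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  classes <- seq_len(max(truth))
  if (!all(classes %in% truth))
    stop("class absent from truth: ",
         paste(setdiff(classes, unique(truth)), collapse = ", "))
  mean(vapply(classes, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1)))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

one_hot <- function(labels, C) {
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Train one model family
#'
#' Dispatcher used by the experiment drivers; `family` is one of `"lr_l1"`,
#' `"lr_l2"`, `"mlp"`, `"gnn"`, `"gbt"`.  Extra arguments are passed to the
#' family's training function.  For `"gnn"` a co-expression graph is built
#' from the training matrix when none is supplied.
#'
#' @param family model family name.
#' @param train a `processed_dataset`.
#' @param seed replicate seed.
#' @param graph optional `correlation_graph` for the GNN.
#' @param ... forwarded to the family trainer.
#' @return a trained model.
#' @export
train_model <- function(family, train, seed = 1L, graph = NULL, ...) {
  switch(family,
    lr_l1 = train_logistic(train, penalty = "l1", seed = seed, ...),
    lr_l2 = train_logistic(train, penalty = "l2", seed = seed, ...),
    mlp = train_mlp(train, seed = seed, ...),
    gnn = {
      if (is.null(graph))
        graph <- build_correlation_graph(train_matrix(train),
                                         edge_budget = 4L * ncol(train$matrix))
      train_gnn(train, graph, seed = seed, ...)
    },
    gbt = train_gbt(train, seed = seed, ...),
    stop_config("unknown model family '", family, "'"))
}

#' Train replicates with distinct seeds
#'
#' @param family model family name.
#' @param train a `processed_dataset`.
#' @param seeds integer vector of replicate seeds.
#' @param ... forwarded to [train_model()].
#' @return list of trained models, one per seed.
#' @export
train_replicates <- function(family, train, seeds, ...)
  lapply(seeds, function(s) train_model(family, train, seed = s, ...))
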