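#' Gradient-boosted decision trees
#'
#' Thin wrapper around xgboost with the training protocol used throughout the
#' package: learning rate 1, single-threaded (which, with fixed
#' hyperparameters, makes training deterministic), logistic / softprob
#' objective.  Per-gene total split gains are recorded as the embedded
#' importance surface.
#'
#' @param train a `processed_dataset`.
#' @param n_estimators boosting rounds.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage (default 1).
#' @param seed recorded replicate seed (training itself is deterministic).
#' @return a `gbt_model` with `feature_importances` (named total gain per
#'   gene, zero for unused genes).
#' @export
train_gbt <- function(train, n_estimators = 50L, max_depth = 4L,
                      learning_rate = 1, seed = 1L) {
  X <- train_matrix(train); y <- train_labels(train)
  C <- train$n_classes
  dtrain <- xgboost::xgb.DMatrix(X, label = y - 1L, nthread = 1L)
  params <- list(max_depth = max_depth, eta = learning_rate, nthread = 1L,
                 seed = as.integer(seed))
  if (C == 2L) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- C
  }
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = n_estimators, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  gains <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(imp) > 0) gains[imp$Feature] <- imp$Gain
  structure(list(model_family = "gbt", booster = booster, n_classes = C,
                 gene_names = colnames(X), feature_importances = gains,
                 replicate_seed = seed),
            class = c("gbt_model", "trained_model"))
}

#' @export
predict_proba.gbt_model <- function(model, X) {
  p <- predict(model$booster,
               xgboost::xgb.DMatrix(X, nthread = 1L))
  if (model$n_classes == 2L) cbind(1 - p, p)
  else if (is.matrix(p)) unname(p)
  else matrix(p, ncol = model$n_classes, byrow = TRUE)
}
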