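#' Penalized logistic regression
#'
#' Binary tasks use a sigmoid head, multi-class tasks a softmax head; both are
#' fit by glmnet at a single fixed penalty (`lambda`).  The input matrix is
#' expected to be standardized already, so coefficient magnitudes are
#' comparable across genes and usable as an embedded importance score.
#'
#' @param train a `processed_dataset`.
#' @param penalty `"l1"` (sparse) or `"l2"` (ridge).
#' @param lambda regularization strength passed to glmnet.
#' @param seed replicate seed (glmnet's coordinate descent is deterministic;
#'   the seed is recorded for the replicate protocol).
#' @param maxit iteration cap; non-convergence warns rather than fails.
#' @return an `lr_model` with logits parameterized as `W` (`C x G`) and `b`
#'   (`C`); for binary tasks the first row of `W` is zero, so softmax over the
#'   two logits equals the sigmoid model.
#' @export
train_logistic <- function(train, penalty = c("l2", "l1"), lambda = 1e-3,
                           seed = 1L, maxit = 1e5) {
  penalty <- match.arg(penalty)
  X <- train_matrix(train)
  y <- train_labels(train)
  C <- train$n_classes
  if (C < 2L) stop_config("need at least two classes")
  alpha <- if (penalty == "l1") 1 else 0
  fam <- if (C == 2L) "binomial" else "multinomial"
  fit <- with_seed(seed, glmnet::glmnet(
    X, factor(y, levels = seq_len(C)), family = fam, alpha = alpha,
    lambda = lambda, standardize = FALSE, maxit = maxit))
  G <- ncol(X)
  if (C == 2L) {
    beta <- as.numeric(fit$beta[, 1L])
    W <- rbind(rep(0, G), beta)
    b <- c(0, fit$a0[[1L]])
  } else {
    W <- t(vapply(fit$beta, function(m) as.numeric(m[, 1L]), numeric(G)))
    b <- as.numeric(vapply(fit$a0, function(a) a[[1L]], numeric(1)))
  }
  colnames(W) <- colnames(X)
  structure(list(model_family = paste0("lr_", penalty), W = W, b = b,
                 n_classes = C, gene_names = colnames(X),
                 replicate_seed = seed),
            class = c("lr_model", "trained_model"))
}

#' @export
predict_proba.lr_model <- function(model, X) {
  Z <- X %*% t(model$W)
  Z <- sweep(Z, 2L, model$b, "+")
  softmax_rows(Z)
}

#' @export
input_gradient.lr_model <- function(model, X, class) {
  P <- predict_proba(model, X)
  # d softmax_c / d x = f_c (W_c - sum_k f_k W_k)
  M <- P %*% model$W
  sweep(-M, 2L, model$W[class, ], "+") * P[, class]
}
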