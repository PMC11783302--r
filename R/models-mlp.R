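#' Multilayer perceptron with batch normalization
#'
#' One or two fully connected hidden layers, each followed by batch
#' normalization and ReLU, then a linear softmax (sigmoid for two classes)
#' head.  Trained by minibatch SGD with momentum on the cross-entropy loss,
#' with weight decay and a step learning-rate schedule; all of it implemented
#' in plain matrix code so the network exposes exact input gradients for
#' attribution methods.
#'
#' @param train a `processed_dataset`.
#' @param hidden_sizes integer vector of length 1 or 2.
#' @param epochs training epochs (default 25).
#' @param batch_size minibatch size.
#' @param lr_schedule named list `list(lr, milestones, factor)`: the learning
#'   rate starts at `lr` and is multiplied by `factor` at each milestone
#'   epoch.  Default 0.1 dropping to 0.01 after epoch 13 and 0.001 after 23.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay on the linear weights.
#' @param seed seed controlling initialization and shuffling.
#' @return an `mlp_model`; its first-layer weights are in `$layers[[1]]$W`.
#' @export
train_mlp <- function(train, hidden_sizes = 32L, epochs = 25L,
                      batch_size = 32L,
                      lr_schedule = list(lr = 0.1, milestones = c(13L, 23L),
                                         factor = 0.1),
                      momentum = 0.9, weight_decay = 1e-4, seed = 1L) {
  if (!length(hidden_sizes) %in% 1:2 || any(hidden_sizes < 1L))
    stop_config("hidden_sizes must hold 1 or 2 positive widths")
  X <- train_matrix(train); y <- train_labels(train)
  C <- train$n_classes; G <- ncol(X); n <- nrow(X)
  eps <- 1e-5
  with_seed(seed, {
    sizes <- c(G, as.integer(hidden_sizes))
    layers <- lapply(seq_along(hidden_sizes), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1L]),
           gamma = rep(1, sizes[l + 1L]), beta = rep(0, sizes[l + 1L]),
           run_mean = rep(0, sizes[l + 1L]), run_var = rep(1, sizes[l + 1L]))
    })
    Wo <- matrix(stats::rnorm(utils::tail(sizes, 1L) * C,
                              sd = sqrt(2 / utils::tail(sizes, 1L))),
                 utils::tail(sizes, 1L), C)
    bo <- rep(0, C)
    vel <- list(layers = lapply(layers, function(l)
      list(W = l$W * 0, gamma = l$gamma * 0, beta = l$beta * 0)),
      Wo = Wo * 0, bo = bo * 0)
    Y <- one_hot(y, C)
    lr <- lr_schedule$lr
    for (epoch in seq_len(epochs)) {
      if (epoch %in% (lr_schedule$milestones + 1L)) lr <- lr * lr_schedule$factor
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs >= 2 rows
        A <- X[idx, , drop = FALSE]
        caches <- vector("list", length(layers))
        for (l in seq_along(layers)) {
          L <- layers[[l]]
          Z <- A %*% L$W
          mu <- colMeans(Z)
          va <- colMeans(sweep(Z, 2L, mu)^2)
          Zh <- sweep(sweep(Z, 2L, mu), 2L, sqrt(va + eps), "/")
          out <- sweep(Zh * rep(L$gamma, each = nrow(Zh)), 2L, L$beta, "+")
          act <- pmax(out, 0)
          caches[[l]] <- list(A_in = A, Zh = Zh, va = va, mask = out > 0)
          layers[[l]]$run_mean <- 0.9 * L$run_mean + 0.1 * mu
          layers[[l]]$run_var <- 0.9 * L$run_var + 0.1 * va
          A <- act
        }
        P <- softmax_rows(sweep(A %*% Wo, 2L, bo, "+"))
        dZ <- (P - Y[idx, , drop = FALSE]) / length(idx)
        gWo <- crossprod(A, dZ) + weight_decay * Wo
        gbo <- colSums(dZ)
        dA <- dZ %*% t(Wo)
        grads <- vector("list", length(layers))
        for (l in rev(seq_along(layers))) {
          ch <- caches[[l]]; L <- layers[[l]]
          dOut <- dA * ch$mask
          gGamma <- colSums(dOut * ch$Zh)
          gBeta <- colSums(dOut)
          dZh <- dOut * rep(L$gamma, each = nrow(dOut))
          nb <- nrow(dZh)
          s1 <- colSums(dZh); s2 <- colSums(dZh * ch$Zh)
          dZl <- sweep(sweep(nb * dZh, 2L, s1) -
                         ch$Zh * rep(s2, each = nb),
                       2L, nb * sqrt(ch$va + eps), "/")
          grads[[l]] <- list(W = crossprod(ch$A_in, dZl) + weight_decay * L$W,
                             gamma = gGamma, beta = gBeta)
          dA <- dZl %*% t(L$W)
        }
        # SGD with momentum
        for (l in seq_along(layers)) {
          for (p in c("W", "gamma", "beta")) {
            vel$layers[[l]][[p]] <- momentum * vel$layers[[l]][[p]] +
              grads[[l]][[p]]
            layers[[l]][[p]] <- layers[[l]][[p]] - lr * vel$layers[[l]][[p]]
          }
        }
        vel$Wo <- momentum * vel$Wo + gWo; Wo <- Wo - lr * vel$Wo
        vel$bo <- momentum * vel$bo + gbo; bo <- bo - lr * vel$bo
        if (anyNA(Wo) || any(!is.finite(Wo)))
          stop("MLP training diverged (non-finite weights)")
      }
    }
    structure(list(model_family = "mlp", layers = layers, Wo = Wo, bo = bo,
                   n_classes = C, gene_names = colnames(X), eps = eps,
                   replicate_seed = seed),
              class = c("mlp_model", "trained_model"))
  })
}

# Inference-mode forward pass; batch norm uses running statistics, so the
# network is a fixed piecewise-linear map.  Returns activations needed for
# the input-gradient backward pass.
mlp_forward <- function(model, X) {
  A <- X
  masks <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    L <- model$layers[[l]]
    Z <- A %*% L$W
    scale <- L$gamma / sqrt(L$run_var + model$eps)
    out <- sweep(Z * rep(scale, each = nrow(Z)), 2L,
                 L$beta - L$run_mean * scale, "+")
    masks[[l]] <- out > 0
    A <- pmax(out, 0)
  }
  P <- softmax_rows(sweep(A %*% model$Wo, 2L, model$bo, "+"))
  list(P = P, masks = masks)
}

#' @export
predict_proba.mlp_model <- function(model, X) mlp_forward(model, X)$P

#' @export
input_gradient.mlp_model <- function(model, X, class) {
  fw <- mlp_forward(model, X)
  P <- fw$P
  # d f_c / d logits = f_c (e_c - f)
  dZ <- -P * P[, class]
  dZ[, class] <- dZ[, class] + P[, class]
  dA <- dZ %*% t(model$Wo)
  for (l in rev(seq_along(model$layers))) {
    L <- model$layers[[l]]
    scale <- L$gamma / sqrt(L$run_var + model$eps)
    dZl <- (dA * fw$masks[[l]]) * rep(scale, each = nrow(dA))
    dA <- dZl %*% t(L$W)
  }
  dA
}
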