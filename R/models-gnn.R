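#' Graph convolutional network on a gene co-expression graph
#'
#' One or two graph convolutional layers with propagation rule
#' `D^{-1/2} (A + I) D^{-1/2} x W` (weights shared across genes), each
#' followed by ReLU and max-pooling over the node pairs merged by one level
#' of heavy-edge-matching coarsening, then a linear softmax head on the
#' flattened node features.  Trained with minibatch Adam on the cross-entropy
#' loss; implemented in plain matrix code so exact input gradients are
#' available for attributions.
#'
#' @param train a `processed_dataset`.
#' @param graph a `correlation_graph` over the same genes.
#' @param n_conv_layers 1 or 2.
#' @param channels integer vector of feature channels per conv layer
#'   (recycled to `n_conv_layers`).
#' @param epochs training epochs (default 15).
#' @param batch_size minibatch size.
#' @param lr_schedule step schedule as in [train_mlp()]; default 0.01
#'   dropping to 0.001 after epoch 8 and 1e-4 after 14.
#' @param weight_decay L2 decay added to the gradients.
#' @param seed seed for initialization and shuffling.
#' @return a `gnn_model`.
#' @export
train_gnn <- function(train, graph, n_conv_layers = 1L, channels = 8L,
                      epochs = 15L, batch_size = 32L,
                      lr_schedule = list(lr = 0.01, milestones = c(8L, 14L),
                                         factor = 0.1),
                      weight_decay = 1e-4, seed = 1L) {
  if (!n_conv_layers %in% 1:2) stop_config("n_conv_layers must be 1 or 2")
  X <- train_matrix(train); y <- train_labels(train)
  C <- train$n_classes; G <- ncol(X); n <- nrow(X)
  if (nrow(graph$adjacency) != G)
    stop_config("graph has ", nrow(graph$adjacency), " nodes but data has ",
                G, " genes")
  channels <- rep_len(as.integer(channels), n_conv_layers)
  # precompute propagation operators and coarsening maps per level
  S <- vector("list", n_conv_layers)
  maps <- vector("list", n_conv_layers)
  g <- graph
  for (l in seq_len(n_conv_layers)) {
    S[[l]] <- normalized_propagation(g$adjacency)
    g <- coarsen_graph(g)
    maps[[l]] <- g$coarsening_maps[[length(g$coarsening_maps)]]
  }
  n_nodes_last <- length(maps[[n_conv_layers]]$first)
  with_seed(seed, {
    fan_in <- c(1L, channels)
    Wc <- lapply(seq_len(n_conv_layers), function(l)
      matrix(stats::rnorm(fan_in[l] * channels[l], sd = sqrt(2 / fan_in[l])),
             fan_in[l], channels[l]))
    bc <- lapply(channels, function(f) rep(0, f))
    d_head <- n_nodes_last * channels[n_conv_layers]
    Wo <- matrix(stats::rnorm(d_head * C, sd = sqrt(1 / d_head)), d_head, C)
    bo <- rep(0, C)
    params <- list(Wc = Wc, bc = bc, Wo = Wo, bo = bo)
    adam_m <- rapply(params, function(p) p * 0, how = "replace")
    adam_v <- adam_m
    t_step <- 0L
    Y <- one_hot(y, C)
    lr <- lr_schedule$lr
    for (epoch in seq_len(epochs)) {
      if (epoch %in% (lr_schedule$milestones + 1L)) lr <- lr * lr_schedule$factor
      perm <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        fw <- gnn_forward(params, S, maps, X[idx, , drop = FALSE], caches = TRUE)
        gr <- gnn_backward(params, S, maps, fw,
                           (fw$P - Y[idx, , drop = FALSE]) / length(idx),
                           weight_decay)
        t_step <- t_step + 1L
        upd <- adam_update(params, gr$grads, adam_m, adam_v, t_step, lr)
        params <- upd$params; adam_m <- upd$m; adam_v <- upd$v
      }
    }
    structure(list(model_family = "gnn", params = params, S = S, maps = maps,
                   channels = channels, n_classes = C,
                   gene_names = colnames(X), replicate_seed = seed),
              class = c("gnn_model", "trained_model"))
  })
}

adam_update <- function(params, grads, m, v, t, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(walk, params, grads, m, v)
  list(params = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
       v = lapply(out, `[[`, "v"))
}

# Forward pass.  Node features are carried as a list of n x G_l matrices, one
# per channel.  Max-pooling is over the (pair, singleton) structure of the
# heavy-edge matching, so each pooled value is max of at most two nodes.
gnn_forward <- function(params, S, maps, X, caches = FALSE) {
  A <- list(X)
  cache <- list()
  for (l in seq_along(S)) {
    P <- lapply(A, function(m) m %*% S[[l]])
    Fo <- ncol(params$Wc[[l]])
    Z <- lapply(seq_len(Fo), function(fo) {
      acc <- matrix(params$bc[[l]][fo], nrow(X), ncol(P[[1L]]))
      for (fi in seq_along(P)) acc <- acc + P[[fi]] * params$Wc[[l]][fi, fo]
      acc
    })
    mask <- lapply(Z, function(m) m > 0)
    H <- Map(function(m, k) m * k, Z, mask)
    mp <- maps[[l]]
    pooled <- lapply(H, function(m) {
      a <- m[, mp$first, drop = FALSE]
      has2 <- !is.na(mp$second)
      if (any(has2)) {
        b <- m[, mp$second[has2], drop = FALSE]
        a[, has2] <- pmax(a[, has2, drop = FALSE], b)
      }
      a
    })
    takefirst <- lapply(H, function(m) {
      has2 <- !is.na(mp$second)
      tf <- matrix(TRUE, nrow(m), length(mp$first))
      if (any(has2))
        tf[, has2] <- m[, mp$first[has2], drop = FALSE] >=
          m[, mp$second[has2], drop = FALSE]
      tf
    })
    if (caches) cache[[l]] <- list(P = P, mask = mask, takefirst = takefirst)
    A <- pooled
  }
  flat <- do.call(cbind, A)
  P_out <- softmax_rows(sweep(flat %*% params$Wo, 2L, params$bo, "+"))
  list(P = P_out, flat = flat, cache = cache, n = nrow(X))
}

# Backward pass from d loss / d logits; returns parameter gradients and the
# gradient with respect to the input gene expression.
gnn_backward <- function(params, S, maps, fw, dLogits, weight_decay = 0) {
  gWo <- crossprod(fw$flat, dLogits) + weight_decay * params$Wo
  gbo <- colSums(dLogits)
  dFlat <- dLogits %*% t(params$Wo)
  L <- length(S)
  Fl <- ncol(params$Wc[[L]])
  Gl <- ncol(dFlat) / Fl
  dPool <- lapply(seq_len(Fl), function(fo)
    dFlat[, (fo - 1L) * Gl + seq_len(Gl), drop = FALSE])
  gWc <- vector("list", L); gbc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    ch <- fw$cache[[l]]; mp <- maps[[l]]
    G_here <- ncol(ch$P[[1L]])
    dH <- lapply(seq_along(dPool), function(fo) {
      dm <- matrix(0, fw$n, G_here)
      tf <- ch$takefirst[[fo]]
      has2 <- !is.na(mp$second)
      dm[, mp$first[!has2]] <- dPool[[fo]][, !has2, drop = FALSE]
      if (any(has2)) {
        d2 <- dPool[[fo]][, has2, drop = FALSE]
        tf2 <- tf[, has2, drop = FALSE]
        dm[, mp$first[has2]] <- d2 * tf2
        dm[, mp$second[has2]] <- d2 * !tf2
      }
      dm
    })
    dZ <- Map(function(dm, k) dm * k, dH, ch$mask)
    Fi <- nrow(params$Wc[[l]])
    gWc[[l]] <- matrix(0, Fi, length(dZ))
    for (fi in seq_len(Fi)) for (fo in seq_along(dZ))
      gWc[[l]][fi, fo] <- sum(ch$P[[fi]] * dZ[[fo]])
    gWc[[l]] <- gWc[[l]] + weight_decay * params$Wc[[l]]
    gbc[[l]] <- vapply(dZ, sum, numeric(1))
    dP <- lapply(seq_len(Fi), function(fi) {
      acc <- matrix(0, fw$n, G_here)
      for (fo in seq_along(dZ)) acc <- acc + dZ[[fo]] * params$Wc[[l]][fi, fo]
      acc
    })
    dPool <- lapply(dP, function(m) m %*% S[[l]])  # S symmetric
  }
  list(grads = list(Wc = gWc, bc = gbc, Wo = gWo, bo = gbo),
       dX = dPool[[1L]])
}

#' @export
predict_proba.gnn_model <- function(model, X)
  gnn_forward(model$params, model$S, model$maps, X)$P

#' @export
input_gradient.gnn_model <- function(model, X, class) {
  fw <- gnn_forward(model$params, model$S, model$maps, X, caches = TRUE)
  P <- fw$P
  dZ <- -P * P[, class]
  dZ[, class] <- dZ[, class] + P[, class]
  gnn_backward(model$params, model$S, model$maps, fw, dZ)$dX
}
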