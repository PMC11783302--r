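# Shared fixtures, all built in code at test time.

# Processed dataset straight from a continuous matrix (no count filtering),
# for model- and attribution-level tests.
toy_processed <- function(X, labels, train_fraction = 0.7, seed = 1L) {
  colnames(X) <- colnames(X) %||% sprintf("G%06d", seq_len(ncol(X)))
  d <- expression_dataset(X, labels)
  sp <- split_samples(d, train_fraction, seed)
  standardize(d, sp$train_index, sp$test_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian two-class data where the first `n_informative` genes carry a mean
# shift of `effect`; linearly separable for large effects.
make_separable <- function(n_per_class = 40L, n_genes = 20L,
                           n_informative = 2L, effect = 3, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * n_genes), n, n_genes,
              dimnames = list(NULL, sprintf("G%06d", seq_len(n_genes))))
  y <- rep(1:2, each = n_per_class)
  X[y == 2L, seq_len(n_informative)] <-
    X[y == 2L, seq_len(n_informative)] + effect
  list(X = X, y = y)
}

# Hand-built binary logistic model (sigmoid head as two-logit softmax).
make_lr <- function(w, b = 0) {
  G <- length(w)
  structure(list(model_family = "lr_l2",
                 W = rbind(rep(0, G), w), b = c(0, b), n_classes = 2L,
                 gene_names = sprintf("G%06d", seq_len(G)),
                 replicate_seed = 0L),
            class = c("lr_model", "trained_model"))
}

# Closed-form integrated gradients for a linear-logit binary model:
# phi_g = (x_g - x'_g) w_g * (sigma(z1) - sigma(z0)) / (z1 - z0).
ig_linear_oracle <- function(w, b, x, xp) {
  sig <- function(z) 1 / (1 + exp(-z))
  z1 <- sum(w * x) + b
  z0 <- sum(w * xp) + b
  slope <- if (abs(z1 - z0) < 1e-12) sig(z0) * (1 - sig(z0))
           else (sig(z1) - sig(z0)) / (z1 - z0)
  (x - xp) * w * slope
}

# Exact hypergeometric upper tail by enumeration over all C(M, n) draws.
hyper_tail_enum <- function(k, K, M, n) {
  draws <- utils::combn(M, n)
  in_set <- seq_len(K)
  mean(apply(draws, 2L, function(d) sum(d %in% in_set) >= k))
}
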