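test_that("logistic regression separates a 2-gene toy and ranks its weight first", {
  set.seed(2)
  X <- matrix(rnorm(100 * 2), 100, 2,
              dimnames = list(NULL, c("G000001", "G000002")))
  y <- ifelse(X[, 1L] > 0, 2L, 1L)  # class = sign of gene 1: separable
  pd <- toy_processed(X, y, train_fraction = 0.9)
  m <- train_logistic(pd, "l2", lambda = 1e-3)
  expect_gt(abs(m$W[2L, 1L]), 5 * abs(m$W[2L, 2L]))
  expect_equal(balanced_accuracy(predict_class(m, train_matrix(pd)),
                                 train_labels(pd)), 1.0)
  P <- predict_proba(m, train_matrix(pd))
  expect_true(all(P >= 0 & P <= 1))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
})

test_that("strong L1 zeroes out most noise-gene coefficients", {
  sep <- make_separable(n_per_class = 40L, n_genes = 100L,
                        n_informative = 2L, effect = 4, seed = 3L)
  pd <- toy_processed(sep$X, sep$y)
  m <- train_logistic(pd, "l1", lambda = 0.05)
  expect_gte(mean(m$W[2L, ] == 0), 0.9)
})

test_that("permuted labels give chance-level training accuracy", {
  sep <- make_separable(n_per_class = 50L, n_genes = 10L, effect = 0,
                        seed = 4L)
  pd <- toy_processed(sep$X, sep$y)
  m <- train_logistic(pd, "l2", lambda = 0.5)
  acc <- balanced_accuracy(predict_class(m, train_matrix(pd)),
                           train_labels(pd))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("the MLP learns XOR, rejects bad widths, and is seed-deterministic", {
  set.seed(6)
  X <- matrix(rnorm(400 * 2, sd = 0.2), 400, 2)
  quad <- sample(1:4, 400, replace = TRUE)
  X[, 1L] <- X[, 1L] + ifelse(quad %in% c(2L, 4L), 1, -1)
  X[, 2L] <- X[, 2L] + ifelse(quad %in% c(3L, 4L), 1, -1)
  y <- ifelse(quad %in% c(1L, 4L), 1L, 2L)  # XOR labelling
  pd <- toy_processed(X, y, train_fraction = 0.8)
  m <- train_mlp(pd, hidden_sizes = 8L, seed = 2L)
  acc <- balanced_accuracy(predict_class(m, train_matrix(pd)),
                           train_labels(pd))
  expect_gte(acc, 0.95)
  expect_error(train_mlp(pd, hidden_sizes = integer(0)), "hidden_sizes")
  expect_error(train_mlp(pd, hidden_sizes = c(4L, 4L, 4L)), "hidden_sizes")
  m2 <- train_mlp(pd, hidden_sizes = 8L, seed = 2L)
  expect_equal(predict_proba(m2, test_matrix(pd)),
               predict_proba(m, test_matrix(pd)))
  # two hidden layers also supported
  m3 <- train_mlp(pd, hidden_sizes = c(8L, 4L), seed = 1L)
  expect_equal(dim(predict_proba(m3, test_matrix(pd))),
               c(length(pd$test_index), 2L))
})

test_that("correlation graph keeps the exact top-|r| edges", {
  set.seed(7)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, sprintf("G%06d", 1:10)))
  X[, 2L] <- X[, 1L]  # duplicate genes: |r| = 1 edge
  g <- build_correlation_graph(X, edge_budget = 5L)
  A <- as.matrix(g$adjacency)
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_equal(A[1L, 2L], 1)
  # brute-force oracle over all pairs
  R <- abs(cor(X)); diag(R) <- 0
  ut <- which(upper.tri(R), arr.ind = TRUE)
  top5 <- ut[order(R[ut], decreasing = TRUE)[1:5], , drop = FALSE]
  kept <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  expect_setequal(paste(top5[, 1L], top5[, 2L]),
                  paste(kept[, 1L], kept[, 2L]))
  expect_error(build_correlation_graph(X, 0L), "edge_budget")
})

test_that("heavy-edge coarsening merges by weight and sums merged edges", {
  # path a-b-c with weights 3 (a,b) and 1 (b,c): merge {a,b}; edge weight 1
  A <- Matrix::sparseMatrix(i = c(1L, 2L), j = c(2L, 3L), x = c(3, 1),
                            dims = c(3L, 3L), symmetric = TRUE)
  g <- structure(list(adjacency = methods::as(A, "generalMatrix"),
                      edge_budget = 2L, coarsening_maps = list()),
                 class = "correlation_graph")
  g2 <- coarsen_graph(g)
  expect_equal(nrow(g2$adjacency), 2L)
  map <- g2$coarsening_maps[[1L]]
  expect_equal(map$cluster[1L], map$cluster[2L])
  expect_false(map$cluster[3L] == map$cluster[1L])
  expect_equal(as.matrix(g2$adjacency)[1L, 2L], 1)
  # edgeless graph: all singletons
  e <- structure(list(adjacency = Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = c(4L, 4L)),
    edge_budget = 1L, coarsening_maps = list()),
    class = "correlation_graph")
  e2 <- coarsen_graph(e)
  expect_equal(nrow(e2$adjacency), 4L)
  # matching bound: node count after one level >= ceiling(G/2)
  set.seed(1)
  X <- matrix(rnorm(40 * 12), 40, 12)
  gg <- coarsen_graph(build_correlation_graph(X, 20L))
  expect_gte(nrow(gg$adjacency), 6L)
})

test_that("normalized propagation matches the 2-node hand computation", {
  A <- Matrix::sparseMatrix(i = 1L, j = 2L, x = 1, dims = c(2L, 2L),
                            symmetric = TRUE)
  S <- geneprofiler:::normalized_propagation(methods::as(A, "generalMatrix"))
  expect_equal(S, matrix(0.5, 2L, 2L), tolerance = 1e-12)
  expect_equal(as.numeric(S %*% c(1, 0)), c(0.5, 0.5))
  # edgeless graph: propagation is the identity (per-gene weight sharing)
  E <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(3L, 3L))
  expect_equal(geneprofiler:::normalized_propagation(E), diag(3))
})

test_that("the GNN trains, predicts, and is seed-deterministic", {
  sep <- make_separable(n_per_class = 40L, n_genes = 20L, n_informative = 4L,
                        effect = 4, seed = 5L)
  pd <- toy_processed(sep$X, sep$y)
  g <- build_correlation_graph(train_matrix(pd), 40L)
  m <- train_gnn(pd, g, seed = 3L)
  acc <- balanced_accuracy(predict_class(m, test_matrix(pd)), test_labels(pd))
  expect_gte(acc, 0.9)
  m2 <- train_gnn(pd, g, seed = 3L)
  expect_equal(predict_proba(m2, test_matrix(pd)),
               predict_proba(m, test_matrix(pd)))
  # dimension mismatch is rejected
  expect_error(train_gnn(pd, build_correlation_graph(
    train_matrix(pd)[, 1:5], 4L)), "nodes")
  # two conv layers run
  m3 <- train_gnn(pd, g, n_conv_layers = 2L, channels = 4L, seed = 1L)
  expect_lt(max(abs(rowSums(predict_proba(m3, test_matrix(pd))) - 1)), 1e-6)
})

test_that("boosted trees find the single informative gene deterministically", {
  set.seed(9)
  X <- matrix(rnorm(120 * 8), 120, 8)
  y <- ifelse(X[, 3L] > 0, 2L, 1L)
  pd <- toy_processed(X, y, train_fraction = 0.8)
  m <- train_gbt(pd, n_estimators = 5L, max_depth = 1L)
  gains <- m$feature_importances
  expect_equal(sum(gains > 0), 1L)
  expect_gt(gains[[3L]], 0)
  m2 <- train_gbt(pd, n_estimators = 5L, max_depth = 1L)
  expect_identical(m2$feature_importances, gains)
  # pure-noise labels with a depth-1 stump: chance-level accuracy
  set.seed(10)
  yn <- sample(1:2, 120, replace = TRUE)
  pdn <- toy_processed(X, yn, train_fraction = 0.8)
  mn <- train_gbt(pdn, n_estimators = 1L, max_depth = 1L)
  accn <- balanced_accuracy(predict_class(mn, train_matrix(pdn)),
                            train_labels(pdn))
  expect_lt(abs(accn - 0.5), 0.2)
})

test_that("balanced accuracy equals the mean per-class recall", {
  expect_equal(balanced_accuracy(c(1L, 2L), c(1L, 2L)), 1.0)
  # recalls 1.0 and 0.5
  expect_equal(balanced_accuracy(c(1L, 1L, 2L, 1L), c(1L, 1L, 2L, 2L)), 0.75)
  # 3-class enumeration oracle
  set.seed(11)
  truth <- rep(1:3, times = c(5L, 7L, 4L))
  pred <- sample(1:3, length(truth), replace = TRUE)
  oracle <- mean(sapply(1:3, function(cl)
    sum(pred == cl & truth == cl) / sum(truth == cl)))
  expect_equal(balanced_accuracy(pred, truth), oracle)
  expect_error(balanced_accuracy(c(1L, 2L), c(2L, 2L)), "absent")
})

test_that("exposed gradients agree with finite differences for all families", {
  sep <- make_separable(n_per_class = 30L, n_genes = 12L, n_informative = 3L,
                        effect = 2, seed = 12L)
  pd <- toy_processed(sep$X, sep$y)
  g <- build_correlation_graph(train_matrix(pd), 24L)
  models <- list(train_logistic(pd, "l2", lambda = 1e-2),
                 train_mlp(pd, hidden_sizes = 6L, seed = 1L),
                 train_gnn(pd, g, seed = 1L))
  set.seed(13)
  eps <- 1e-5
  for (m in models) {
    for (rep in 1:5) {
      x <- train_matrix(pd)[sample(nrow(train_matrix(pd)), 1L), ]
      gr <- input_gradient(m, matrix(x, 1L), 2L)
      i <- which.max(abs(gr))
      xp <- x; xp[i] <- x[i] + eps
      xm <- x; xm[i] <- x[i] - eps
      fd <- (predict_proba(m, matrix(xp, 1L))[, 2L] -
               predict_proba(m, matrix(xm, 1L))[, 2L]) / (2 * eps)
      expect_lt(abs(fd - gr[i]) / max(abs(fd), 1e-8), 1e-4)
    }
  }
  expect_error(input_gradient(train_gbt(pd), train_matrix(pd), 2L),
               "not defined")
})

test_that("multi-class heads produce valid probabilities and gradients", {
  set.seed(14)
  X <- matrix(rnorm(180 * 10), 180, 10)
  y <- rep(1:3, each = 60L)
  for (cl in 1:3) X[y == cl, cl] <- X[y == cl, cl] + 3
  pd <- toy_processed(X, y)
  for (m in list(train_logistic(pd, "l2", lambda = 1e-2),
                 train_mlp(pd, hidden_sizes = 8L, seed = 1L),
                 train_gbt(pd, n_estimators = 20L, max_depth = 2L))) {
    P <- predict_proba(m, test_matrix(pd))
    expect_equal(ncol(P), 3L)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-6)
    acc <- balanced_accuracy(predict_class(m, test_matrix(pd)),
                             test_labels(pd))
    expect_gte(acc, 0.8)
  }
})

test_that("replicate seed lists yield stable lr top-100 overlap", {
  sep <- make_separable(n_per_class = 60L, n_genes = 150L,
                        n_informative = 10L, effect = 3, seed = 15L)
  pd <- toy_processed(sep$X, sep$y)
  reps <- train_replicates("lr_l2", pd, seeds = 1:3, lambda = 1e-2)
  rankings <- lapply(reps, rank_lr_weights)
  for (i in 1:2) {
    ov <- length(intersect(top_genes(rankings[[i]], 100L),
                           top_genes(rankings[[i + 1L]], 100L)))
    expect_gte(ov, 90L)
  }
})

test_that("every family exceeds 0.95 balanced accuracy on well-separated data", {
  cfg <- synthetic_config(n_samples_per_class = c(200L, 200L),
                          n_genes = 300L, n_de_genes_per_class = 20L,
                          log2_fold_change = 3, seed = 71L)
  pd <- preprocess(generate_counts(cfg)$dataset, seed = 1L)
  for (fam in c("lr_l1", "lr_l2", "mlp", "gnn", "gbt")) {
    m <- train_model(fam, pd, seed = 1L)
    acc <- balanced_accuracy(predict_class(m, test_matrix(pd)),
                             test_labels(pd))
    expect_gte(acc, 0.95)
  }
})
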