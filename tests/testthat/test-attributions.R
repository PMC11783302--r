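test_that("integrated gradients match the linear-logit closed form", {
  # W = (1, 0), b = 0, x = (2, 0), x' = 0: phi = (sigma(2) - sigma(0), 0)
  m <- make_lr(c(1, 0))
  phi <- integrated_gradients(m, c(2, 0), c(0, 0), target_class = 2L,
                              n_steps = 1024L)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(unname(phi[1L]), sig(2) - sig(0), tolerance = 1e-6)
  expect_equal(unname(phi[2L]), 0)
  # general closed-form oracle on a random linear model
  set.seed(1)
  w <- rnorm(6); b <- 0.3; x <- rnorm(6); xp <- rnorm(6)
  m2 <- make_lr(w, b)
  phi2 <- integrated_gradients(m2, x, xp, 2L, n_steps = 1024L)
  expect_equal(as.numeric(phi2), ig_linear_oracle(w, b, x, xp),
               tolerance = 1e-6)
  # sample equal to baseline: all scores zero
  phi3 <- integrated_gradients(m2, x, x, 2L, n_steps = 16L)
  expect_equal(as.numeric(phi3), rep(0, 6L))
  expect_error(integrated_gradients(structure(list(), class = "gbt_model"),
                                    x, xp, 2L), "gradient-based")
})

test_that("completeness holds and the residual shrinks with more steps", {
  sep <- make_separable(n_per_class = 30L, n_genes = 10L, n_informative = 3L,
                        effect = 2, seed = 2L)
  pd <- toy_processed(sep$X, sep$y)
  g <- build_correlation_graph(train_matrix(pd), 20L)
  models <- list(mlp = train_mlp(pd, hidden_sizes = 6L, seed = 1L),
                 gnn = train_gnn(pd, g, seed = 1L))
  x <- train_matrix(pd)[1L, ]
  bl <- attribution_baseline(pd)
  steps <- c(16L, 32L, 64L, 128L, 256L, 512L)
  for (m in models) {
    res <- sapply(steps, function(s)
      attr(integrated_gradients(m, x, bl, 2L, n_steps = s),
           "completeness_residual"))
    expect_lt(res[[6L]], 1e-3)
    # overall shrinkage; ReLU kinks make the decrease non-strict step to step
    expect_lt(res[[6L]], res[[1L]])
    expect_true(all(res <= 2 * res[[1L]]))
  }
  # smooth logistic integrand: strictly monotone midpoint-rule convergence
  m_lr <- train_logistic(pd, "l2", lambda = 1e-2)
  res_lr <- sapply(steps, function(s)
    attr(integrated_gradients(m_lr, x, bl, 2L, n_steps = s),
         "completeness_residual"))
  expect_true(all(diff(res_lr) < 1e-12))
})

test_that("class aggregation normalizes to unit vectors and averages", {
  # one sample with local scores (3, 4) -> (0.6, 0.8)
  expect_equal(aggregate_class_scores(list(c(3, 4))), c(0.6, 0.8))
  # two identical samples: same as one
  expect_equal(aggregate_class_scores(list(c(3, 4), c(3, 4))), c(0.6, 0.8))
  # 5-sample toy equals a brute-force loop over the definition
  set.seed(3)
  loc <- lapply(1:5, function(i) rnorm(7))
  got <- aggregate_class_scores(loc)
  acc <- rep(0, 7)
  for (v in loc) acc <- acc + abs(v) / sqrt(sum(v^2))
  expect_equal(got, acc / 5, tolerance = 1e-12)
  nrm <- sapply(loc, function(v) sqrt(sum((abs(v) / sqrt(sum(v^2)))^2)))
  expect_equal(nrm, rep(1, 5), tolerance = 1e-12)
  expect_true(all(got >= 0))
  # all-zero local vectors are dropped with a warning
  expect_warning(z <- aggregate_class_scores(list(c(3, 4), c(0, 0))),
                 "all-zero")
  expect_equal(z, c(0.6, 0.8))
})

test_that("global aggregation averages class vectors", {
  expect_equal(aggregate_global(list(c(1, 0))), c(1, 0))
  expect_equal(aggregate_global(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(4)
  vs <- lapply(1:3, function(i) runif(5))
  expect_equal(aggregate_global(vs), (vs[[1L]] + vs[[2L]] + vs[[3L]]) / 3,
               tolerance = 1e-12)
  expect_error(aggregate_global(list(1:2, 1:3)), "length")
})

test_that("the prediction gap reproduces the hand-worked curve", {
  # construct a 2-gene logistic model with f(x) = 0.8, then 0.6, 0.2 as the
  # genes are masked in ranking order: PG = (0.25 + 0.75) / 2 = 0.5
  logit <- function(p) log(p / (1 - p))
  b <- logit(0.2)
  w <- c(logit(0.8) - logit(0.6), logit(0.6) - logit(0.2))
  m <- make_lr(w, b)
  rk <- gene_ranking(c(G000001 = 2, G000002 = 1), "toy")
  pg <- prediction_gap(m, c(1, 1), rk, "important_first", c(0, 0),
                       target_class = 2L)
  expect_equal(pg$outputs, c(0.8, 0.6, 0.2), tolerance = 1e-12)
  expect_equal(pg$pg_value, 0.5, tolerance = 1e-12)
  expect_gte(pg$pg_value, 0); expect_lte(pg$pg_value, 1)
  # m = 0 reproduces f_c(x) exactly
  expect_equal(pg$outputs[1L], 0.8, tolerance = 1e-12)
  # a constant model has PG = 0 under any order
  m0 <- make_lr(c(0, 0), 0.4)
  for (o in c("important_first", "unimportant_first", "random"))
    expect_equal(prediction_gap(m0, c(1, 1), rk, o, c(0, 0),
                                target_class = 2L)$pg_value, 0)
})

test_that("PGI exceeds PGU for a correct single-informative-gene ranking", {
  G <- 20L
  w <- c(6, rep(0, G - 1L))
  m <- make_lr(w, 0)
  x <- rep(1, G); ref <- rep(-1, G)
  scores <- setNames(c(1, runif(G - 1L) * 0.1), m$gene_names)
  rk <- gene_ranking(scores, "truth")
  pgi <- prediction_gap(m, x, rk, "important_first", ref,
                        target_class = 2L)$pg_value
  pgu <- prediction_gap(m, x, rk, "unimportant_first", ref,
                        target_class = 2L)$pg_value
  expect_gt(pgi, pgu)
  # only the top gene matters: PGU ~ 1/G
  expect_lt(pgu, 2 / G)
  # reversed ranking swaps the roles
  rk_rev <- gene_ranking(setNames(-scores, names(scores)), "reversed")
  pgi_rev <- prediction_gap(m, x, rk_rev, "important_first", ref,
                            target_class = 2L)$pg_value
  expect_equal(pgi_rev, pgu, tolerance = 0.1)
})

test_that("IG ranking puts the planted informative gene on top across seeds", {
  hits <- 0L
  for (s in 1:10) {
    sep <- make_separable(n_per_class = 25L, n_genes = 15L,
                          n_informative = 1L, effect = 4, seed = 100L + s)
    pd <- toy_processed(sep$X, sep$y, seed = s)
    m <- train_logistic(pd, "l2", lambda = 1e-2, seed = s)
    r <- rank_integrated_gradients(m, pd, n_steps = 32L,
                                   max_samples_per_class = 10L)
    hits <- hits + (top_genes(r, 1L) == "G000001")
  }
  expect_gte(hits, 9L)
})

test_that("baselines follow the binary and multi-class conventions", {
  sep <- make_separable(n_per_class = 10L, n_genes = 4L, seed = 5L)
  pd <- toy_processed(sep$X, sep$y)
  bl <- attribution_baseline(pd)
  tr <- pd$matrix[pd$train_index, , drop = FALSE]
  ytr <- pd$labels[pd$train_index]
  expect_equal(bl, colMeans(tr[ytr == 1L, , drop = FALSE]))
  # multi-class: global training mean
  set.seed(6)
  X <- matrix(rnorm(90 * 4), 90, 4)
  pd3 <- toy_processed(X, rep(1:3, each = 30L))
  expect_equal(attribution_baseline(pd3),
               colMeans(pd3$matrix[pd3$train_index, , drop = FALSE]))
})
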