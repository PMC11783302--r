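#' Default end-to-end run configuration
#'
#' Desk-scale demonstration settings: a two-class negative-binomial dataset,
#' the full preprocessing chain, a configurable set of model families with a
#' replicate seed list, rankings by every method, prediction-gap masking,
#' retraining curves, the top-k overlap matrix and ORA against a planted-truth
#' GMT collection.
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds are derived from it.
#' @return a `run_config` list.
#' @export
default_run_config <- function(out_dir = tempfile("gp_run_"), seed = 1L) {
  list(out_dir = out_dir, seed = as.integer(seed),
       synthetic = synthetic_config(
         n_samples_per_class = c(100L, 100L), n_genes = 1000L,
         n_de_genes_per_class = 30L, log2_fold_change = 2.5,
         n_redundant_blocks = 5L, block_size = 10L,
         block_correlation = 0.7, block_log2_fc = 1.5, seed = seed),
       train_fraction = 0.6,
       families = c("lr_l1", "lr_l2", "mlp", "gbt"),
       n_replicates = 3L,
       filter_methods = c("var", "pca", "mi", "de"),
       retrain_grid = c(10L, 50L, 100L),
       retrain_family = "lr_l2",
       ig_steps = 64L, pg_stride = 4L, pg_samples = 10L,
       ora_top_n = 50L)
}

write_csv_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the whole profiling pipeline
#'
#' Generates (or loads) a dataset, applies the preprocessing chain, trains
#' every configured model family over the replicate seed list, derives all
#' gene rankings (filter, embedded, integrated gradients), runs the masking
#' experiment, retraining on top/bottom/random subsets, the overlap matrix
#' and ORA, and writes every table as CSV with a JSON manifest of seeds and
#' configuration.  Deterministic stages are bit-identical across reruns with
#' the same config.
#'
#' @param config a `run_config`, see [default_run_config()]; set
#'   `config$data` to an [expression_dataset()] to analyse external data
#'   instead of simulating.
#' @return invisibly, a list with all in-memory results (`processed`,
#'   `models`, `rankings`, `exp0`, `retrain`, `overlap`, `ora`, `accuracy`).
#' @export
run_full_pipeline <- function(config = default_run_config()) {
  known <- c("lr_l1", "lr_l2", "mlp", "gnn", "gbt")
  if (!all(config$families %in% known))
    stop_config("unknown model family: ",
                paste(setdiff(config$families, known), collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)

  if (!is.null(config$data)) {
    data <- config$data; truth <- NULL
  } else {
    sim <- generate_counts(config$synthetic)
    data <- sim$dataset; truth <- sim$truth
  }
  pd <- preprocess(data, train_fraction = config$train_fraction,
                   seed = seeds[1L])
  rep_seeds <- derive_seeds(seeds[2L], config$n_replicates)

  models <- lapply(config$families, function(fam)
    if (fam == "gbt") list(train_model(fam, pd, seed = rep_seeds[1L]))
    else train_replicates(fam, pd, rep_seeds))
  names(models) <- config$families

  accuracy <- do.call(rbind, lapply(config$families, function(fam) {
    accs <- vapply(models[[fam]], function(m)
      balanced_accuracy(predict_class(m, test_matrix(pd)), test_labels(pd)),
      numeric(1))
    data.frame(family = fam, balanced_accuracy_mean = mean(accs),
               balanced_accuracy_sd = ifelse(length(accs) > 1,
                                             stats::sd(accs), 0))
  }))
  write_csv_out(accuracy, config$out_dir, "balanced_accuracy")

  tr <- train_matrix(pd); ytr <- train_labels(pd)
  de <- rank_differential_expression(tr, ytr)
  filter_rankings <- list()
  for (m in config$filter_methods) {
    filter_rankings[[m]] <- switch(m,
      var = rank_variance(tr), pca = rank_pca(tr),
      mi = rank_mutual_information(tr, ytr), de = de$ranking,
      stop_config("unknown filter method '", m, "'"))
  }
  rankings <- lapply(filter_rankings, list)
  for (fam in config$families) {
    if (fam %in% c("lr_l1", "lr_l2"))
      rankings[[paste0(fam, "_weight")]] <-
        lapply(models[[fam]], rank_lr_weights)
    if (fam == "gbt")
      rankings[["gbt_gain"]] <- lapply(models[[fam]], rank_gbt_gain)
    if (fam %in% c("lr_l1", "lr_l2", "mlp", "gnn"))
      rankings[[paste0(fam, "_ig")]] <- lapply(models[[fam]], function(m)
        rank_integrated_gradients(m, pd, n_steps = config$ig_steps,
                                  max_samples_per_class = config$pg_samples))
  }
  for (nm in names(rankings))
    write_ranking(rankings[[nm]][[1L]],
                  file.path(config$out_dir, paste0("ranking_", nm, ".tsv")))

  ov <- overlap_matrix(rankings)
  utils::write.csv(ov$matrix, file.path(config$out_dir, "overlap_matrix.csv"))

  # experiment 0 on the first gradient-based family with IG rankings
  exp0 <- NULL
  fam0 <- intersect(config$families, c("lr_l1", "lr_l2", "mlp", "gnn"))[1L]
  if (!is.na(fam0)) {
    exp0 <- run_experiment_0(models[[fam0]],
                             rankings[[paste0(fam0, "_ig")]], pd,
                             max_samples = config$pg_samples,
                             stride = config$pg_stride)
    write_csv_out(data.frame(family = fam0, pgi = exp0$pgi_mean,
                             pgi_sd = exp0$pgi_sd, pgu = exp0$pgu_mean,
                             pgu_sd = exp0$pgu_sd,
                             maskable_pct = exp0$maskable_pct),
                  config$out_dir, "experiment0_pg")
  }

  base_rank <- rankings[["de"]][[1L]] %||% rankings[[1L]][[1L]]
  retrain <- lapply(c("top", "bottom", "random"), function(sel)
    run_retrain_experiment(pd, base_rank, config$retrain_family,
                           grid = config$retrain_grid, selection = sel,
                           seeds = rep_seeds[1L]))
  names(retrain) <- c("top", "bottom", "random")
  write_csv_out(do.call(rbind, lapply(names(retrain), function(s)
    cbind(selection = s, retrain[[s]]))), config$out_dir, "retrain_curves")

  ora <- NULL
  if (!is.null(truth) && length(unlist(truth$de_gene_indices_by_class))) {
    gmt <- generate_toy_gmt(truth, n_decoy_sets = 10L, seed = seeds[3L])
    firsts <- lapply(rankings, `[[`, 1L)
    ora <- ora_report(firsts, gmt, top_n = config$ora_top_n)
    write_csv_out(do.call(rbind, lapply(names(ora$tables), function(m)
      cbind(method = m, utils::head(ora$tables[[m]], 10L)))),
      config$out_dir, "ora_top_sets")
  }

  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   replicate_seeds = rep_seeds,
                   families = config$families,
                   n_genes_kept = ncol(pd$matrix),
                   n_train = length(pd$train_index),
                   n_test = length(pd$test_index))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(processed = pd, truth = truth, models = models,
                 rankings = rankings, accuracy = accuracy, overlap = ov,
                 exp0 = exp0, retrain = retrain, ora = ora,
                 out_dir = config$out_dir))
}
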