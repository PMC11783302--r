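# geneprofiler

Classifiers trained on bulk RNA-seq count matrices — penalized logistic
regression, shallow multilayer perceptrons, graph convolutional networks on
gene co-expression graphs, and gradient-boosted trees — can all be asked the
same question: *which genes drive the prediction of the phenotype?*
`geneprofiler` is an R package for asking that question carefully.  It
implements the main families of per-gene importance scores and the
evaluation machinery needed to compare them, for bioinformaticians and
machine-learning researchers who want to know whether a "top genes" list is
a property of the biology or of the method that produced it.

## What it computes

**Rankings.** Filter statistics (variance, first-principal-component
loadings `|v¹_g|`, k-NN mutual information `I(X_g; Y)`, Welch unequal-variance
t-tests scored as `−log10(adjusted p)` with BH correction), embedded scores
(`|W_g|` of a logistic regression, or the class-average `(1/C) Σ_c |W_cg|`;
total split gain of boosted trees), and integrated-gradients attributions

    φ_g(x) = (x_g − x'_g) ∫₀¹ ∂f_c/∂x_g (x' + α(x − x')) dα,

aggregated per class as the mean of `|φ|/‖φ‖` over correctly classified
training samples and then averaged over classes.  The MLP and GNN are
implemented in plain matrix code with analytic backpropagation, so exact
input gradients are available (finite-difference checked to 1e-4).

**Evaluations.** Prediction-gap curves under progressive masking —
`PG = (1/G) Σ_m max(f_c(x) − f_c(x̃_m), 0)/f_c(x)`, most-important-first
(PGI) or least-important-first (PGU) — retraining from scratch on top-,
bottom- and randomly ranked gene subsets with balanced accuracy (mean
per-class recall) on held-out samples, top-10/top-100 overlap matrices
across methods and replicates, and hypergeometric over-representation
analysis against GMT gene-set collections with FDR control.

**Simulation.** A negative-binomial generator with planted differentially
expressed genes, configurable effect sizes and class imbalance, and
redundant gene blocks driven by a shared latent factor whose loading is
solved in closed form to hit a target pairwise correlation.  The planted
truth makes recovery, calibration and redundancy claims testable without
any external download.

## Worked example

```r
library(geneprofiler)

cfg <- synthetic_config(n_samples_per_class = c(100L, 100L), n_genes = 500L,
                        n_de_genes_per_class = 20L, log2_fold_change = 2,
                        seed = 1L)
sim <- generate_counts(cfg)
sim$dataset
#> <expression_dataset> 200 samples x 500 genes, 2 classes
#>   samples per class: 100/100

pd <- preprocess(sim$dataset, seed = 1L)   # filter, log2-CPM, split, z-score
pd
#> <processed_dataset> 200 samples (120 train / 80 test) x 420 genes, 2 classes

model <- train_logistic(pd, penalty = "l2", seed = 1L)
balanced_accuracy(predict_class(model, pd$matrix[pd$test_index, ]),
                  pd$labels[pd$test_index])
#> [1] 1

ig <- rank_integrated_gradients(model, pd, n_steps = 64L)
de <- rank_differential_expression(pd$matrix[pd$train_index, ],
                                   pd$labels[pd$train_index])

planted <- sim$truth$gene_names[unlist(sim$truth$de_gene_indices_by_class)]
sum(top_genes(ig, 40L) %in% planted)
#> [1] 40

round(overlap_matrix(list(ig = ig, de = de$ranking))$matrix, 1)
#>     ig  de
#> ig 100  81
#> de  90 100

x <- pd$matrix[pd$train_index[1L], ]
prediction_gap(model, x, ig, "unimportant_first",
               attribution_baseline(pd), target_class = 2L)$pg_value
#> [1] 0.002817905
```

Reading the output: the classifier is perfect on held-out data; integrated
gradients recover all 40 planted genes in their top 40; the IG and Welch-DE
rankings share 90% of their top 10 and 81% of their top 100; and the PGU of
~0.0028 (G = 420, so 1/G ≈ 0.0024) says the model's decision survives until
essentially only the top-ranked genes remain unmasked — the trained model
relies on a very small set of genes.

`run_full_pipeline(default_run_config())` wires all of this end to end
(training replicates of every family, all rankings, masking experiment,
retraining curves, overlap matrix, ORA) and writes CSV tables plus a JSON
manifest to the configured output directory.

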