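---
title: "Methods: comparative gene-expression profiling with geneprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative gene-expression profiling with geneprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneprofiler)
```

## Scope and data model

`geneprofiler` compares ways of ranking genes by their importance for a
phenotype classifier trained on bulk RNA-seq counts.  A dataset is a matrix
of nonnegative read counts, samples in rows and genes in columns, with one
class label per sample (tumour type, subtype, or healthy/tumour status).
Three families of ranking methods are covered:

* **filter statistics** that ignore any classifier — per-gene variance,
  loadings on the first principal component, mutual information with the
  class, and a Welch unequal-variance t-test for differential expression;
* **embedded scores** read off a trained model — coefficient magnitudes of a
  penalized logistic regression, total split gain of boosted trees;
* **post-hoc attributions** — integrated gradients computed on any
  gradient-exposing classifier (logistic regression, multilayer perceptron,
  or a graph convolutional network on a gene co-expression graph).

Rankings are then judged in four ways: prediction-gap masking curves,
retraining on ranked gene subsets, top-k overlap between methods and
replicates, and hypergeometric over-representation analysis (ORA) against
gene-set collections in GMT format.

## The synthetic-data generator

Real tumour compendia cannot be redistributed with a package, so every
stage is exercised on simulated data whose structure mirrors such cohorts:
two to tens of classes with strong imbalance, on the order of $10^3$–$10^4$
genes, counts with overdispersion, a minority of genes carrying class
signal, and blocks of strongly correlated (redundant) genes.

Counts are negative binomial with `variance = mu + mu^2 * dispersion`, the
parameterization assumed by the standard differential-expression tools.
Per-gene baseline means are `2^u` with `u` uniform on
`baseline_mean_log_range` (default 0–10 on the log2 scale), so the
low-count filter sees both regimes.  The default dispersion of 0.05 is in
the range typically estimated for bulk RNA-seq within a homogeneous sample
group.  A gene planted as differentially expressed for class $c$ has its
mean multiplied by $2^{\mathrm{lfc}}$ in that class; planted sets are
disjoint across classes, so recovery can be scored unambiguously.

Redundant blocks share a standard-normal latent factor $z$ added on the
log-mean scale with loading $a$: $\mu_{gn} = \mu_g e^{a z_n}$.  Writing
$m_1 = e^{a^2/2}$ and $m_2 = e^{2a^2}$, the count-scale moments are

$$\mathrm{Var}\,X = \mu m_1 + \mu^2\big((1+\phi)m_2 - m_1^2\big), \qquad
\mathrm{Cov}(X_1, X_2) = \mu^2 (m_2 - m_1^2),$$

and the loading is solved by root finding so the implied pairwise Pearson
correlation equals `block_correlation`.  The correlation is bounded by
roughly $1/(1+\phi)$; an unreachable target is a configuration error rather
than a silent miss.  Block baseline means are drawn from the upper half of
the mean range so shot noise does not drown the latent signal.  The
optional `block_log2_fc` field additionally shifts each block in one class
(round-robin assignment), which is how the package builds datasets where
*every* gene carries signal — the regime in which low-ranked genes are
known to remain informative.  The generator does **not** emulate batch
effects, library-size/class confounding, or tissue-specific covariance
beyond these blocks; passing tests therefore demonstrate correctness of the
machinery, not performance claims about any real cohort.

## Preprocessing conventions

Filtering removes, in order, genes with missing values, genes that are zero
everywhere, and low-expressed genes with fewer than 5 counts in more than
75% of samples *in every class*.  The per-class quantifier is deliberate: a
gene silent in all classes but one is a plausible marker and is kept; the
stricter "any class" reading is available via `quantifier = "any"`.
Normalization is counts-per-million followed by `log2(1 + x)`; the
pseudocount of 1 keeps zero counts finite and leaves CPM scale invariance
intact.  Samples with zero total counts are an error naming the sample.

The train/test split (default 60/40) is stratified by class — with strong
imbalance a plain random split can starve a small class — using
round-half-up per class and a ±1 adjustment toward the global target.
Standardization uses training-set means and *population* (1/N) standard
deviations applied to all samples; test statistics never enter, and
near-zero deviations fall back to 1 with a warning.

## Classifiers

Four families are implemented behind a common surface
(`predict_proba()`, `input_gradient()`, `train_model()`):

* **lr_l1 / lr_l2** — penalized logistic regression fit by glmnet at a
  single fixed penalty (default `lambda = 1e-3`), sigmoid head for two
  classes and softmax otherwise.  The convex objective has a unique
  optimum, so replicates differ only nominally.
* **mlp** — one or two fully connected hidden layers (default one layer of
  32 units), each with batch normalization and ReLU, softmax head; trained
  by minibatch SGD with momentum 0.9, weight decay $10^{-4}$, 25 epochs,
  learning rate 0.1 stepped down 10× after epochs 13 and 23.
* **gnn** — a graph convolutional network on the gene co-expression graph:
  propagation $D^{-1/2}(A+I)D^{-1/2} x W$ with weights shared across genes,
  ReLU, then max-pooling over node pairs merged by one level of greedy
  heavy-edge-matching coarsening (merged edge weights are summed), a second
  conv/pool level optionally, and a linear softmax head; trained with Adam
  for 15 epochs, learning rate 0.01 stepped down after epochs 8 and 14.
  The graph keeps the `edge_budget` strongest $|r|$ Pearson edges computed
  on training samples; absolute values keep the symmetric normalization
  well defined when correlations are negative.
* **gbt** — gradient-boosted trees through xgboost, learning rate 1,
  single-threaded and hence deterministic at fixed hyperparameters; total
  per-gene split gain is the embedded importance.

The MLP and GNN are implemented directly in matrix code rather than through
a deep-learning framework so that exact input gradients are available for
attribution; finite-difference agreement at $10^{-4}$ relative error is
part of the test suite.  At inference, batch normalization uses running
statistics, making each network a fixed piecewise-linear map.
Classification quality is reported as balanced accuracy (mean per-class
recall), which is insensitive to class imbalance.

## Gene rankings

All rankings share one container: higher score = more important, rank 1 is
best, and ties break lexicographically by gene name so every ranking is a
reproducible permutation (the tie rule is recorded in the file header).

* variance uses the population $1/N$ convention;
* the PCA score is $|v^1_g|$ from the leading covariance eigenvector
  (sign-indeterminate, harmless under the absolute value; a near-degenerate
  leading eigenvalue warns);
* mutual information uses a k-nearest-neighbour estimator (default
  $k = 3$) for continuous expression against the discrete class, in nats,
  negative estimates clipped at 0; a tiny fixed-seed jitter breaks the ties
  produced by log-CPM zeros;
* differential expression is a per-gene Welch t-test on log-CPM values,
  all class pairs for multi-class tasks, minimal raw p per gene, then
  Benjamini–Hochberg across genes, scored as $-\log_{10}(\text{adjusted }p)$.
  Externally computed DESeq2/edgeR tables enter through `read_ranking()` on
  the same score scale; the package deliberately does not reimplement the
  negative-binomial GLM tests.
* logistic-regression weights: $|W_g|$ (binary) or the class-mean of
  $|W_{cg}|$; boosted-tree gain: total gain, unused genes exactly 0.

## Integrated gradients and prediction gaps

For a sample $x$, baseline $x'$ and target class $c$,

$$\phi_g(x) = (x_g - x'_g)\int_0^1
\frac{\partial f_c}{\partial x_g}\Big(x' + \alpha(x - x')\Big)\,d\alpha,$$

approximated with a midpoint Riemann sum (default 128 steps).  The
completeness identity $\sum_g \phi_g = f_c(x) - f_c(x')$ is reported as a
residual with every call; on the smooth logistic model the residual falls
monotonically with the step count, while for ReLU networks the decrease is
overall but not strictly monotone because the integrand's kinks move
relative to the grid.  Baselines follow the binary convention (mean of
normal-class training samples) or the multi-class one (global training
mean), both overridable.

Per-class aggregation averages $|\phi|/\lVert\phi\rVert$ over correctly
classified training samples of the class; all-zero attribution vectors are
dropped with a warning rather than propagating NaN.  The global score is
the class mean; binary tasks attribute the tumour class only.

The prediction gap masks genes one at a time, substituting baseline values,
and accumulates $\max(f_c(x) - f_c(\tilde x_m), 0)/f_c(x)$ over mask sizes
$m = 1..G$, divided by $G$.  Masking most-important-first gives PGI,
least-important-first PGU, and a seeded random order is available for the
random-gene comparison.  A stride option evaluates every $k$-th mask size
for large gene sets; the scalar is then an average over the strided grid
and labelled as such by the caller's choice of stride.

## Experiments, overlap, ORA

Experiment 0 aggregates PGI/PGU over (up to a cap of) correctly classified
training samples, then across model replicates (mean ± sd), also reporting
$100 - 100\cdot\mathrm{PGI}$, the percentage of top genes that can be masked
before the model is disturbed.  Experiments 1 and 2 retrain a family from
scratch on the $g$ best- or worst-ranked genes (or random ones) and report
balanced accuracy on the held-out test set; the default grid is
$\{1, 5, 10, 50, 100, 500, 1000\}$ capped at $G$ rather than every integer
up to 1000, each ranking replicate paired with one retraining seed; the
GNN rebuilds its graph on the gene subset.  The overlap matrix averages
top-10 (lower triangle) and top-100 (upper triangle and diagonal)
percentages over replicate pairs and masks methods whose nonzero-score
gene count cannot fill the list.  The Welch-t diagnostic reports the
Spearman correlation of any ranking with $|t|$ and compares the top-100
$|t|$ distribution against a random 100.

ORA tests each gene set by the exact hypergeometric upper tail against the
post-filter gene universe — the MSigDB web annotator uses its own
background, so real-data comparisons are qualitative — with BH control
across sets, a $q \le 0.05$ cutoff, the top 10 sets displayed per method,
and cross-flags against other methods' top-100 significant sets.  Methods
with fewer nonzero-score genes than the list size use all their nonzero
genes.

## Numerical choices and degenerate inputs

Scores must be finite (NaN is an error, not a silent drop); zero-variance
genes get p = 1 with a warning in the Welch test; constant genes contribute
zero correlation to the graph; `f_c(x) = 0` makes the prediction gap
undefined and errors; empty significant-set lists in ORA are reported
empty.  All randomness flows from explicit seeds through one derivation
helper, and the RNG state of the caller is always restored.

## Problem sizes used by the packaged runs

The demonstration pipeline and the packaged checks run at desk scale, the
package's own choice for a reproducible default: 2 classes at 100 samples
each, 1000 genes (30 planted DE per class, five 10-gene redundant blocks at
correlation 0.7), 3 model replicates, 64 integration steps and a stride of
4 on the masking curves.  Recovery and calibration checks use 500 genes at
100 samples per class over five seeds; the redundancy retraining check uses
260 genes in which every gene carries signal.  Larger runs only require
changing the configuration.

## Known limitations

Hyperparameters are fixed defaults (a config-driven grid search is out of
scope); the GNN uses greedy heavy-edge matching rather than Graclus; the
simulator's redundancy model is a single shared factor per block; ORA is
enrichment-only (no depletion, no ranked GSEA); and no claims are made
about reproducing numbers measured on controlled-access human cohorts.
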