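---
title: "Methods: signature construction and mixture deconvolution in celldecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction and mixture deconvolution in celldecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldecon)
```

## The linear mixing model

The package rests on one assumption: the expression of a gene in a bulk
sample is the proportion-weighted sum of its expression in the cell types
the sample contains,

$$ m_g = \sum_c S_{gc}\, f_c + \varepsilon_g, \qquad f_c \ge 0,\ \sum_c f_c = 1 . $$

Additivity only holds on the **linear** expression scale, which drives
several choices below: signature entries are linear (CPM-scale) means, not
log values; mixing in the simulator happens on linear CPM; and solvers
operate on linear inputs (the ν-SVR standardization is an affine map, which
preserves the mixing structure).

The estimated `f` is relative to total measured immune content. The
non-immune share of a tissue (tumor cells, stroma) is deliberately not
modeled: a sample that is 99% tumor still yields fractions describing the
remaining 1% immune compartment. Absolute-abundance estimation is out of
scope.

## Signature gene matrix construction

`build_signature()` takes raw counts of labeled pure-cell samples and runs:

1. **voom transform.** Counts become
   $\log_2\!\big((\mathrm{count}+0.5)/(\mathrm{libsize}+1)\times 10^6\big)$,
   and each observation receives a precision weight from a lowess trend
   (span 0.5, configurable) of $\sqrt{\text{residual sd}}$ against mean
   log2 count, fitted under the group-means design so between-type
   differences do not inflate residual variance. This is the limma voom
   construction; weights make count heteroscedasticity compatible with
   linear modeling.
2. **One-vs-rest moderated DE per cell type.** A weighted least-squares fit
   of log expression on the target-vs-rest indicator; residual variances
   are shrunk toward a common prior by empirical Bayes (scaled-F model,
   method-of-moments prior), giving moderated t-statistics with
   `df.residual + df.prior` degrees of freedom, and BH-adjusted two-sided
   p-values. With the prior's weight taken to zero the moderated t reduces
   to the classic weighted t — the shrinkage only stabilizes small-sample
   variance estimates. One-vs-rest is used because the goal is markers
   specific to each type against the pooled background of all others.
3. **Three filters**, with strict inequalities throughout: adjusted
   P `< 0.05` **and** log2 fold change `> 2` (upregulated only); optional
   removal of genes whose expression in any supplied non-hematopoietic or
   tumor profile exceeds that profile's 0.95 expression quantile; and
   maximum raw count across all pure samples `≥ 100`. The tissue filter's
   quantile rule is this package's explicit, tunable criterion for "highly
   expressed elsewhere"; 0.95 flags roughly the top 5% of a profile, and
   the filter is a no-op when no profiles are supplied.
4. **Top-k ranking.** Survivors are ordered per type by decreasing log2
   fold change (ties: smaller adjusted P, then lexicographic gene ID) and
   the top 20 taken. The union over types forms the signature gene list; a
   gene selected for two types is kept once, attributed to the type with
   the larger fold change, so rows stay unique.

Signature entries are the **mean quantile-normalized linear CPM** of each
signature gene over the pure samples of each type. The training reference
distribution (the mean of sorted CPM columns) is stored with the signature
so that new samples can be mapped onto the training scale.

## Quantile normalization and the reference bundle

`quantile_normalize()` replaces each column's values by reference quantiles
at the column's ranks; ties receive the mean of the tied reference
quantiles ("ties = average"), which keeps the map deterministic and
symmetric. With a fixed reference the operation is idempotent, and with the
default reference all columns end up with identical sorted values (exact up
to float rounding, provided values are tie-free).

Which reference to use is a genuine design choice: normalizing each dataset
against its own pool makes results depend on batch composition. The package
therefore carries the **training** reference inside the signature bundle
and, by default, maps new mixtures onto it (`deconvolve(...,
normalize = "reference")`), making single-sample deconvolution
deterministic and training-consistent. When mixtures are already on the
training scale — as the package's own simulated benchmarks are, being
generated directly on CPM — normalization is skipped
(`normalize = "none"`): forcing a mixture's flatter value distribution onto
the pure-cell reference would only distort it.

## The six solvers

All methods share gene alignment (exact string match after whitespace
stripping) and, except QP, the post-processing convention for reporting
relative proportions: negative coefficients clamped to zero, then division
by the sum (an all-nonpositive vector becomes all-zero, flagged
degenerate).

* **llsr** — unconstrained ordinary least squares, then clamp/renormalize.
  Rank-deficient signatures are rejected with the collinear columns named.
* **qp** — minimizes $\|Sf-m\|^2$ subject to $f \ge 0,\ \sum f = 1$
  (Goldfarb–Idnani dual method). The system is pre-scaled by
  $\max|S_{gc}|$ — the argmin is scale-invariant — and the Gram matrix gets
  a ridge of $10^{-10}\,\overline{\mathrm{diag}}$ so the factorization
  stays stable on CPM-scale inputs; both perturbations are orders of
  magnitude below solution tolerances. The output is already a proportion
  vector.
* **ridge / lasso / elastic_net** — glmnet with penalty mixing 0, 1, 0.5;
  no intercept, standardized inputs; λ selected on a 100-point log-spaced
  grid ($10^{-4}$–$10^2$) by 5-fold cross-validation over genes. Fold
  membership is derived from the seed and the *sort order of gene IDs*, so
  permuting gene rows cannot change the selected λ — solver output is
  row-permutation equivariant by construction.
* **nu_svr** — the CIBERSORT protocol: genes are observations, cell types
  features; the signature matrix is standardized **globally** (one mean and
  SD over all entries) and the mixture z-scored over genes; linear-kernel
  ν-SVR with C = 1 is fitted at ν ∈ {0.25, 0.5, 0.75} and the ν with the
  smallest RMSE between fitted values and the z-scored mixture wins; the
  primal weight vector over cell types is returned. Global (not
  per-column) standardization matters: z-scoring each cell-type column
  separately would rescale columns relative to one another and break the
  mixing interpretation of the weights. Because the mixture is z-scored,
  fractions are invariant to any positive rescaling of the input sample.
  The SVM termination tolerance is tightened to $10^{-9}$ so the converged
  weights do not depend on gene-row order.

Per-sample diagnostics record reconstruction RMSE and correlation on the
solver's working scale plus the chosen hyperparameter (λ or ν). Samples are
solved independently — the mixing model is per-sample — and a failure in
one sample is recorded in its row without aborting the batch.

## The synthetic benchmark

`simulate_benchmark()` stands in for a real training/evaluation corpus.
Defaults, chosen once as a realistic desk-scale study:

| parameter | default | meaning |
|---|---|---|
| `n_cell_types` | 10 | immune panel size |
| `n_genes` | 1000 | gene space |
| `markers_per_type` | 20 | planted marker genes per type (disjoint) |
| `marker_log2fc` | 4 | marker elevation, log2 scale |
| `replicates_per_type` | 4 | pure-cell samples per type |
| `nb_dispersion` | 0.1 | negative-binomial overdispersion of counts |
| `noise_sd_log2` | 0.1 | multiplicative mixture noise, log2 SD |
| `tumor_fractions` | 0 … 0.999 | spike-in grid, reaching 99.9% tumor |
| `n_mixtures` | 20 | Dirichlet(1) fraction vectors |

Baseline per-gene means are log-normal (median 100, sdlog 1.2) and shared
across types; markers are shifted up by `marker_log2fc`; replicate counts
are negative-binomial. Mixing fractions are symmetric Dirichlet(1) —
uniform on the simplex, maximally uninformative. Mixtures are formed on
linear CPM, noise is applied to the immune mixture, and the tumor profile
is blended in as $(1-c)\,m + c\,T$.

The **tumor profile** is an independent log-normal profile over the same
gene space with its own 50-gene high-expression program. Immune marker
genes are silenced to a 1% leaky floor of their baseline draw — a tumor
cell line does not express lineage-restricted immune genes — except for a
5% contaminated subset expressed at ordinary baseline level, emulating the
handful of immune-adjacent genes real cell lines do express. This
contamination is the stressor that separates robust solvers from fragile
ones at high tumor content: in the shipped benchmark the ν-SVR degrades
most gracefully toward 99.9% tumor, while unpenalized least squares is
increasingly sensitive to the contaminated genes — the pattern that
motivates preferring SVR for tumor tissue.

What the simulator does **not** emulate: correlated expression programs
between related lineages (CD4 vs CD8 T cells are far harder to separate in
real data than disjoint-marker types), library-size and batch effects,
platform differences, zero-inflation, and a real cell line's transcriptome.
Passing benchmarks here demonstrates correctness of the machinery and the
solvers' relative robustness ordering, not field performance on real
tissue.

## Numerical and degenerate-input conventions

* Threshold comparisons are strict exactly as documented (`< 0.05`,
  `> 2`; max count `< 100` is dropped, `= 100` kept).
* Argmax ties in pure-sample identification count as *not identified*
  (conservative and deterministic); the tie rule for marker ranking is
  fold change, then adjusted P, then gene ID.
* A constant mixture vector is an error for ν-SVR (z-scoring undefined);
  an all-zero post-processed fraction vector is flagged, not thrown.
* All generators are reproducible from a single integer seed; sub-streams
  (profiles, fractions, tumor, per-mixture noise) use fixed offsets from
  it, so partial re-runs are stable.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the default simulation
(1000 genes, 40 pure samples, 160 mixtures), a 200-gene exact-recovery
system, 50 random 2- and 3-type instances against a dense simplex grid
(step $10^{-3}$), and small fixtures for the unit oracles — sizes chosen so
the full suite exercises every code path at desk scale in a few minutes.

## Known limitations

* Fractions are relative to the immune compartment; tumor purity is not
  estimated.
* No hierarchical lineage modeling; each cell type is a flat category.
* The tissue-expression filter needs user-supplied non-immune profiles;
  without them it is a no-op.
* Mapping mixtures onto the training reference assumes the mixture's gene
  set matches the training gene space; mixtures with a different gene
  universe should be deconvoluted with `normalize = "none"` after their
  own normalization.
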