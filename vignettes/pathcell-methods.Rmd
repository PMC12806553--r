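---
title: "Methods: pathway-activity classification of tumor cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-activity classification of tumor cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `pathcell`, the choices
that were genuinely open when it was built, and what its synthetic benchmark
does and does not demonstrate.

## The featurization: pathway activity scores

Raw scRNA-seq counts are dominated by technical zeros. A classifier built on
single marker genes inherits that sparsity; a classifier built on gene-set
summaries does not, because a pathway of 25–60 genes rarely loses all of its
members to dropout at once. `pathcell` uses the simplest such summary:

1. each cell is scaled to a common library size `target_sum`
   (default 10,000 counts, the de facto convention) and `log1p`-transformed;
2. the score of pathway $P$ in cell $c$ is the mean of the normalized values
   over the pathway genes present in the matrix, **zeros included**.

Two deliberate consequences. First, zeros are data: tumor cells tend to
detect more genes than normal cells, and averaging with zeros keeps that
detection-rate signal in every pathway score. Second, genes in a pathway but
absent from the expression matrix are *ignored* rather than treated as
zero — absence from the matrix is a property of the reference, not of the
cell — and the per-pathway number of matched genes is reported
(`n_genes_used`). Pathways matching fewer than `min_genes` genes
(default 3) are dropped: a "mean" over one or two genes defeats the purpose
of pooling.

The score formula is isolated in `score_pathways()`; swapping in a
rank-based scheme (AUCell-style) would touch nothing downstream.

## Feature selection

At training time each pathway is tested with a two-sided Wilcoxon rank-sum
test of tumor versus normal scores; pathways with $p < 0.05$ are retained,
with **no** multiplicity correction — this is a screening filter, where a
false positive costs one near-noise feature and a false negative discards
real signal. For *reporting*, `differential_pathways()` applies the stricter
rule $|\mathrm{log_2FC}| > 1$ and Benjamini–Hochberg FDR $< 0.05$, with
$\mathrm{log_2FC} = \log_2\frac{\bar s_T + \epsilon}{\bar s_N + \epsilon}$
and pseudocount $\epsilon = 0.01$ guarding pathways whose mean score is zero
in one class. The two rules are separate operations because they serve
different stages (feature screening versus biology reporting).

The rank-sum p-value is exact when both groups have at most 8 cells —
computed from the null distribution of the Mann–Whitney U statistic when
there are no ties, by complete enumeration over all
$\binom{n_1+n_2}{n_1}$ assignments (with midranks) when there are — and
otherwise uses the normal approximation with tie and continuity corrections.
Pooled-constant scores get $p = 1$ by convention. The exact small-sample
branch doubles as an internal oracle: the test suite checks it against an
independently written brute-force enumeration and against
`stats::wilcox.test`.

## The classifier

A fully connected network: input ($P$ selected pathways) → 128 ReLU →
dropout → 64 ReLU → dropout → 1 sigmoid, trained with Adam
(learning rate $10^{-3}$, batch 256) on binary cross-entropy, with
per-pathway standardization (population SD; zero-variance pathways get
scale 1) fitted on the training cells and embedded in the model. A
stratified internal validation fold (10% of training cells) drives early
stopping with patience 10 over at most 200 epochs; the best-validation
weights are kept. For a feature space of ~100 pathways and $10^3$–$10^5$
cells this capacity is ample; the architecture is configurable and recorded
in the model artifact, so none of these defaults is load-bearing.

Cells with probability ≥ 0.5 are called tumor (ties break toward tumor,
the positive class). Metrics use tumor-positive conventions and report 0
for zero-denominator precision/recall/F1, so a degenerate all-negative
predictor scores 0 rather than being silently undefined.

Determinism: the trainer draws initialization, batch shuffles, dropout
masks and splits from a seed recorded in the model; the same data and seed
reproduce bit-identical weights. Model artifacts serialize every numeric as
a `%.17g` string inside JSON, which round-trips doubles exactly (generic
JSON number formatting does not).

## Permutation importance

Importance of pathway $p$ = mean increase in evaluation-set binary
cross-entropy when $p$'s *standardized* score row is shuffled across cells,
over `n_repeats` (default 100) fresh permutations, each seeded
deterministically from (seed, pathway, repeat). Shuffling after
standardization means the scaler is never refit — the measurement isolates
how the trained model uses the feature. Δloss is computed on held-out
cells: importance should describe the model's generalizing behavior, not
its memorization. Ranking ties break lexicographically by pathway name so
reports are deterministic.

A known limitation, which the package's own benchmark exhibits: when many
features carry *correlated* copies of the same signal, single-column
permutation divides importance among them. On the synthetic benchmark below,
the detection-rate difference between classes leaks a modest amount of
signal into every pathway's score (by design — see the featurization), so
the classifier spreads reliance across many redundant features and planted
pathways beyond the strongest few do not monopolize the top ranks. A convex
model (logistic regression) fitted to the same features spreads its weights
the same way, confirming this is a property of the data conditions and the
importance definition, not of the network. On data where a few pathways
carry all the class signal, the top ranks recover them exactly.

## Robustness protocols

Two degradation operators, each leaving matrix shapes and label alignment
untouched:

- **Gene retention** — per cell, keep a uniform random subset of
  `min(n_retain, n_detected)` of its *detected* genes and zero the rest,
  then re-normalize and re-score from scratch. Operating per cell on
  detected genes matches how real cells differ in detected-gene depth.
  Default levels: 100, 200, 500, 1000, 2000, 5000 genes.
- **Pathway inactivation** — zero a uniform random
  $\lfloor f \cdot P \rfloor$ of the standardized score rows at predict
  time. Zeroing (the training mean) rather than shuffling is the operator
  here because shuffling preserves a feature's marginal distribution and
  thus some signal, while "inactivation" should remove the feature's
  information entirely; the operator is isolated in
  `inactivate_pathways()` for substitution. Default fractions: 0–0.8 in
  steps of 0.2.

Both feed `robustness_curve()`, which reports per-level mean ± SD of
F1/accuracy/precision/recall over replicate draws (default 10).
`top_pathway_ablation()` complements them: train one model on only the
top-$k$ pathways of an importance table and one on all-but-top-$k$, and
compare held-out metrics.

## The synthetic generator

`generate_dataset()` draws from the minimal generative structure under
which pathway-mean scoring provably pools signal:

- genes are partitioned into non-overlapping pathways (sizes uniform in
  `genes_per_pathway`); real KEGG-style collections overlap heavily, so
  overlap would blur planted-truth recovery — non-overlap is the default
  for testability, not realism;
- per-gene baseline means are lognormal(`baseline_mean_log_mu` = −1.5,
  `baseline_mean_log_sd` = 1), i.e. a median mean of ≈0.22 counts and
  ≈1,800 counts per cell over 5,000 genes, droplet-like;
- tumor cells multiply the means of "up" pathway genes by
  $2^{\text{effect}}$ and "down" genes by $2^{-\text{effect}}$, so the
  reported log2FC has a known target *direction* (not an exact value —
  scores are nonlinear in means);
- counts are negative binomial (`dispersion` = 0.5, i.e. substantial
  biological-plus-technical overdispersion), with tumor means additionally
  scaled by `tumor_library_scale` (default 1.5) to reproduce the higher
  detected-gene counts of tumor cells;
- entries are then zeroed with probability
  $\mathrm{logistic}(-\text{slope}\,(\log \mu - \text{midpoint}))$
  (midpoint −1, slope 1: ≈50% dropout at a mean of $e^{-1}$), the standard
  mean-dependent dropout model.

The frozen benchmark (`make_acceptance_dataset()`) is 1,000 + 1,000 cells,
5,000 genes, 100 pathways, 10 up + 10 down planted at one log2 unit,
dispersion 0.5, library scale 1.5, with a stratified 8:2 split. These sizes
keep a full pipeline run (generation through evaluation) around ten seconds
on one CPU while leaving enough cells per split for stable metrics. For the
ablation contrast a separate configuration plants exactly 4 pathways
(2 up + 2 down, library scale 1 so those four carry *all* class signal) in
500 + 500 cells, 2,000 genes, 50 pathways.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, copy-number structure, cell-type mixtures within the normal
compartment, or matching of real-data marginals. Passing the synthetic
benchmark therefore demonstrates that the pipeline's machinery is correct
and robust under NB-plus-dropout sparsity with planted effects — not that
its accuracy transfers to any particular tissue or platform. Null
configurations (`effect_log2fc = 0`, `tumor_library_scale = 1`) make the
classes exchangeable and are used to check test calibration (retained
fraction ≈ α) and chance-level classification.

## Numerical conventions

- Sigmoid outputs are clamped to $[10^{-7}, 1-10^{-7}]$ inside the
  cross-entropy so saturated predictions cannot produce infinite loss.
- Population (not sample) SD in the scaler; zero-variance features scale 1.
- `floor(fraction * P + 1e-9)` when counting pathways to inactivate, so
  decimal fractions like 0.6 are not truncated by floating-point error.
- Per-(unit, repeat) seeds derive from a 31-bit multiplicative hash of the
  base seed, keeping every derived seed a valid R integer and making
  per-pathway work order-independent.
- Duplicate gene symbols (after uppercase/whitespace canonicalization) are
  summed on read; symbol canonicalization is applied identically to count
  matrices and GMT files so joins cannot silently fail on case.

## Known limitations

- The pathway score is a stand-in for any more elaborate activity measure;
  it is deliberately the simplest formula consistent with sparsity pooling.
- Permutation importance under heavily redundant features understates
  individual contributions (see above).
- The rank-sum screen pools all cells; per-dataset or per-cancer-type
  stratified testing is out of scope.
- The classifier ships untrained: real-data use requires the user's own
  labeled training cells.
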