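---
title: "Dysregulated miRNA-target networks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysregulated miRNA-target networks: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dysmir)
```

## The problem and the model

Most miRNA network studies in cancer rank miRNAs by how strongly their own
expression (or their targets' expression) changes between tumor and normal
tissue. `dysmir` implements the complementary idea: score how much the
*regulatory relation itself* rewires. For a candidate miRNA--mRNA pair
$(i, j)$ the dysregulation score is

$$ S_{ij} = \lvert \rho_{ij}^{(t)} - \rho_{ij}^{(n)} \rvert, $$

where $\rho^{(t)}$ and $\rho^{(n)}$ are the within-condition Spearman
correlations across tumor and normal samples. $S$ lives in $[0, 2]$: a pair
that flips from perfectly positive to perfectly negative coupling scores 2,
a pair whose coupling is condition-independent scores 0 regardless of how
strong that coupling is.

Significance comes from a label-permutation null: the tumor/normal
partition is shuffled (jointly for both members of the pair, preserving
group sizes and sample identity), $S$ is recomputed, and the p-value is the
fraction of permutations whose score meets or exceeds the observed one.
Pairs with $p < 0.05$ (strict, unadjusted) form the directed bipartite
dysregulated miRNA-target network (DMTN). Downstream, five per-miRNA
features — out-degree, number of co-regulating miRNAs, percentage of
co-regulators that are known disease miRNAs, number of targets shared with
disease miRNAs, and log2 fold change of mean expression — feed an RBF-SVM
whose cost and kernel width are tuned by a real-coded genetic algorithm
maximizing mean stratified 5-fold cross-validated AUC. A score cutoff (the
"recognition threshold") is set just above the highest score of any
true-negative training miRNA, so by construction zero TN miRNAs are called
risk. The remaining modules are screens around that core: hypergeometric
set overlaps with BH adjustment, median-split Kaplan--Meier/log-rank
survival, Spearman immune-infiltration associations, and a Pearson
IC50-vs-expression drug screen thresholded at $\lvert r\rvert \ge 0.2$ and
BH $q < 0.05$.

## Conventions that matter (and why)

* **Correlation flavor.** The source formula is written "PCC" but defined
  in words as Spearman; both readings are kept as a `method` switch with
  Spearman the default, since rank correlation is the natural choice for
  normalized RNA-seq abundances with heavy tails.
* **Permutation tail.** Ties count against the observed score
  ($S_\mathrm{perm} \ge S_\mathrm{obs}$), keeping the p-value valid; ties
  have essentially measure zero on continuous data. The plain fraction can
  return 0; a `(count+1)/(B+1)` pseudo-count variant sits behind a flag,
  default off.
* **Reproducible parallel-safe streams.** Each pair's permutations come
  from an mt19937 stream seeded by `(seed, pair index)` with an explicit
  Fisher--Yates shuffle, so results do not depend on pair order, chunking,
  or platform.
* **Exhaustive mode.** For tiny designs the permutation distribution is
  enumerated over all $\binom{n}{n_t}$ tumor-subset choices (capped,
  default 10,000 partitions); the Monte-Carlo path is tested against this
  enumeration.
* **Edge rule.** $p < \alpha$ is strict, and edges are *not*
  multiplicity-adjusted by default, matching the raw-$p$ screen the method
  was described with; a BH option exists.
* **Degenerate pairs.** A constant expression vector within a condition
  makes the correlation undefined; such pairs are skipped with a recorded
  reason rather than assigned $p = 1$.
* **Low-expression filter.** A feature is dropped iff its fraction of
  exact zeros among *normal* samples exceeds 10% (strict "more than";
  exactly 10% is kept). Tumor samples never influence the decision; a
  switch to filter on all samples exists, default off. Zero means exactly
  0.0 — the inputs are count-derived normalized values, so no epsilon.
* **Recognition threshold.** "Recognition rate" is implemented as the
  normative rule its description implies: the smallest probability-like
  cutoff at which no TN training miRNA is called positive
  (`nextafter(max TN score)`), with prediction strictly above it. The
  0.825 value quoted for the original cohort is a cohort-specific
  realization of this rule, not a constant of the method.
* **Score calibration.** libsvm's internal probability machinery is not
  seed-stable, so scores are mapped to $[0,1]$ by a Platt-style sigmoid
  fitted on *out-of-fold* decision values of the winning hyperparameters;
  the final SVM is refit on all labeled data. Feature standardization is
  computed on training folds only — no leakage into validation folds.
* **GA design** (the source is silent): genome = $(\log_{10} C,
  \log_{10}\gamma) \in [-2,3] \times [-3,1]$, population 20, 15
  generations, tournament size 3, uniform crossover $p = 0.5$, Gaussian
  mutation $\sigma = 0.3$, elitism 2, fitness = mean 5-fold AUC. A coarse
  3×3 grid search is available as a baseline (`search = "grid"`), and a
  property test requires the GA to match it within 0.02 AUC.
* **Ranking ties.** `rank_sum_negatives` breaks rank-sum ties
  lexicographically by miRNA id; `median_split` sends values equal to the
  median to the low group (both configurable) — determinism over elegance.
* **Survival conventions.** Events are processed before censorings at tied
  times (standard); direction of effect is read off the restricted-mean
  survival difference between the high and low group; both raw p and BH q
  are reported since the original analysis does not state an adjustment.
* **Screens.** The immune screen defaults to Spearman and the drug screen
  to Pearson, following their respective method descriptions; the drug
  threshold $\lvert r \rvert \ge 0.2$ is inclusive. BH q-values are always
  computed within one screen, never pooled across screens. Missing IC50
  entries are handled pairwise-complete with a minimum-n guard (default
  20 paired observations).
* **Hypergeometric tail.** The displayed overlap formula in the source is
  typographically mangled; the implementation is the standard upper tail
  $P(X \ge x) = 1 - \sum_{t=0}^{x-1} \binom{M}{t}\binom{N-M}{K-t} /
  \binom{N}{K}$, evaluated in log space (`phyper`), and is tested against
  exact rational arithmetic. Set elements outside the declared universe
  are dropped with a warning, never added to $N$.

## What the synthetic data emulates

The generator produces every input the pipeline consumes, with
machine-readable ground truth, so all stages are testable without any
cohort download.

* **Expression.** Per-condition bivariate Gaussian copulas with log-normal
  marginals. A planted pair with Spearman target $\rho$ uses the Pearson
  parameter $2\sin(\pi\rho/6)$ on the latent scale, the exact
  Spearman-Pearson relation for bivariate Gaussians, so the realized rank
  correlation matches the target without tuning. Dysregulated pairs get
  $(\rho_t, \rho_n)$ = (0.6, 0.0) by default; null fillers link
  independent features; an equal-$\rho$ configuration
  (`null_scenario_config()`) gives the exchangeable null.
* **Risk structure.** A risk block (20% of miRNAs) receives most of the
  planted out-degree, membership in two partially overlapping curated
  disease lists (plus decoy ids), and a log2 fold change of 1.5. A
  low block (25%) has strictly dominated mean and variance in every
  sample subset, so the six-ranking negative selection has a provably
  correct answer, and exactly one planted pair each so it appears in the
  network. The null-calibration scenario instead uses one miRNA and one
  gene per pair so that pair-level p-values are mutually independent and
  the fraction below 0.05 concentrates tightly around its expectation.
* **Survival.** Exponential event times with log-hazard linear in the
  standardized log-expression of the driving features; independent
  exponential censoring whose rate is solved (root finding on the expected
  censoring probability) to hit a 30% target.
* **Immune abundances.** Dirichlet compositions via normalized Gamma
  draws, with a dominated concentration profile (two large cell types,
  the rest sparse) mimicking typical deconvolution output. Planted
  feature-cell-type couplings go through a Gaussian copula on the Gamma
  variate; because row normalization attenuates the realized rank
  correlation, the generator estimates that attenuation by an internal
  Monte-Carlo draw and inflates the latent coupling accordingly, and
  plants on sparse components where the attenuation is mild.
* **Drug response.** Log-scale IC50 columns built as linear Gaussian
  mixes with the *expression values* of planted features (coupling the
  latent normals instead would attenuate the realized Pearson r by ~15%
  under log-normal marginals), plus 10% missing entries at random.

What it deliberately does **not** emulate: read-count noise (negative
binomial), batch effects, subtype structure, miRNA-name aliasing, or
realistic linkage between the survival, immune and drug layers beyond the
planted couplings. Passing tests therefore demonstrate correctness of the
statistical machinery under a controlled model, not robustness to every
real-data pathology.

## Problem sizes and defaults

The default desk-scale scenario is 60+60 samples, 150 miRNAs, 600 genes,
2,000 candidate pairs of which 200 are rewired, and 1,000 permutations per
pair; the whole pipeline completes in well under ten minutes on one CPU.
`n_perm = 10000` (the original screen's depth) remains the function
default for `permutation_pvalues()`; the pipeline default of 1,000 trades
p-value granularity (1/1000) for speed and is ample for $\alpha = 0.05$
screens. The rank-sum negative pool is `k_negatives = 40` at desk scale —
proportional to the 95-of-1,881 used at cohort scale. Calibration and
power checks use 1,000 independent null pairs at 50+50 samples and 200
planted pairs at 100+100 samples respectively.

## Known limitations

* The permutation p-value granularity is $1/B$; with the plain fraction a
  perfectly separable pair reports $p = 0$ (use the pseudo-count flag when
  downstream tooling dislikes zeros).
* The out-degree log-log slope is a descriptive statistic over non-empty
  degree bins, not a maximum-likelihood power-law fit, and no goodness of
  fit is claimed.
* Shortest paths are computed on the undirected bipartite graph (miRNA to
  miRNA via a shared target = 2); analyses that want the miRNA-projection
  distance should halve them.
* With small TN sets the Platt sigmoid can saturate, pushing the
  recognition threshold close to 0 or 1; the zero-TN guarantee holds
  regardless, but the numeric threshold is then not comparable across
  runs.
* `survival_screen` uses the restricted mean to orient effects; for
  crossing hazards the direction label is a summary, not a test.
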