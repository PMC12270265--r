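---
title: "Simulating genotype arrays and risk scores from summary statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genotype arrays and risk scores from summary statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genetic risk scores (GRS) compress trait-associated genotype variation
into one number per person. Evaluating a GRS across cohorts usually
requires the individual-level genotypes of each cohort, which are often
unshareable for ethical, legal or logistic reasons. The quantities that
*can* usually be released are aggregate: per-SNP allele frequencies,
pairwise dosage correlations (linkage disequilibrium), and — where a SNP
departs from Hardy–Weinberg equilibrium (HWE), e.g. through population
stratification or case ascertainment — its genotype-class proportions.
`grsim` reconstructs a genotype array consistent with exactly these
statistics and scores it, so GRS distributions, case/control
discrimination (ROC/AUC) and array structure (PCA) can be compared
without the original data.

# The simulation model

## Marginals first, exactly

Write the array as $X \in \{0,1,2\}^{N\times p}$, dosages counting a
designated allele per SNP. Columns are initialized independently:

* **SNP in HWE, frequency $f$:** each entry is
  $\mathrm{Bern}(f)+\mathrm{Bern}(f)$ — one draw per chromosome copy —
  giving genotype-class probabilities $((1-f)^2,\,2f(1-f),\,f^2)$.
* **SNP out of HWE, fractions $(\phi_0,\phi_1,\phi_2)$:** the column
  contains exactly $\mathrm{round}(\phi_g N)$ copies of each genotype
  (largest-remainder rounding, so counts sum to $N$), in uniformly
  random order. This matches the stated class proportions as closely as
  integer counts allow.

## Correlations by within-column permutation

Only pairs whose target correlation passes a threshold are matched:
adjacency is $|r| \ge$ `corr_threshold` (default 0.1, the conventional
cut below which LD estimates are treated as noise). Connected
components of this graph are optimized independently — SNPs in
different components share no constraint. For a group with $l$ kept
edges the loss is the mean squared deviation of realized from target
Pearson correlations,
$$\mathrm{loss} = \frac{1}{l}\sum_{j=1}^{l}(\hat\rho_j-\rho_j)^2 .$$

The optimizer's only move is to exchange **one SNP's** values between
two samples. Such a move permutes a column, so genotype counts — and
hence frequencies, HWE fractions, column means and variances — are
conserved *exactly*; only cross-products change. A "pass" visits every
ordered SNP pair of the group in random order; per pair it draws a fresh
random permutation of samples and walks its $\lfloor N/2\rfloor$
adjacent disjoint sample pairs, exchanging the swapped SNP's two values,
keeping the exchange iff the loss strictly decreases, reverting
otherwise. Iteration stops as soon as the loss reaches `tolerance`, the
attempt budget is spent, or an optional wall-clock limit expires.

Because column moments are invariant, the implementation maintains only
the per-edge sums $S_{xy}=\sum_i x_i y_i$ and updates each candidate in
$O(\text{edges incident to the swapped SNP})$. A tested property keeps
this incremental loss within $10^{-9}$ of a from-scratch evaluation at
every accepted state.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `corr_threshold` | 0.1 | correlation | below this, LD is treated as chance noise and not targeted |
| `tolerance` | 0.03 | squared correlation | group is "converged" when the mean squared edge deviation falls below it |
| `iteration_limit` | 10000 | passes' worth of attempts | budget is `iteration_limit * floor(N/2)` attempted exchanges per group |
| `n_samples` | 5000 | samples | size of the simulated cohort |
| `seed` | — | — | master seed; per-group substreams derive from `(seed, group_index)` |

The defaults mirror the reference experimental settings for a 65–67 SNP
type 1 diabetes GRS.

# Numerical and design choices

* **Correlation measure.** Signed Pearson $r$ on dosage columns. The
  loss compares $\hat\rho$ to $\rho$ *with sign*, so the optimizer needs
  direction; the adjacency threshold is applied to $|r|$. (LD servers
  often threshold on $R^2$; users who prefer that convention can square
  the cut themselves — thresholding $|r|$ at $t$ equals thresholding
  $r^2$ at $t^2$.)
* **HWE detection.** Chi-square goodness of fit of observed genotype
  counts against $((1-f)^2, 2f(1-f), f^2)$, 1 df, no continuity
  correction, default $\alpha = 0.05$. Monomorphic SNPs are treated as
  consistent with HWE (the test is undefined) and excluded from the
  correlation table with a warning (their correlation is undefined too).
* **Tie handling.** An exchange that leaves the loss unchanged is
  reverted: accepting ties would let the optimizer random-walk on
  plateaus without progress, and would break the strict-decrease
  invariant that the instrumented tests check.
* **Which column moves.** The toy semantics exchange values within a
  single column between two samples. Iterating over *ordered* SNP pairs
  gives every column of a pair swap opportunities within a pass while
  keeping each move marginal-preserving.
* **Iteration accounting.** "Iteration limit" is ambiguous between
  passes and attempted exchanges; we count attempted exchanges with
  budget `iteration_limit × floor(N/2)` and additionally report whole
  passes, so both readings are visible in the report.
* **Non-convergence** is reported (`converged = FALSE`, best-so-far
  state kept), never raised: a group that cannot reach the tolerance is
  still the best available array.
* **Determinism.** Identical inputs and seed give a bit-identical
  matrix and report. Group substreams are derived from
  `(seed, group_index)`, so per-group results do not depend on the
  order groups are processed. The one non-deterministic output byte
  sequence is `elapsed_seconds` in the report JSON — wall-clock time
  cannot be reproducible, and we chose to keep it in the report rather
  than drop a useful field.

# The GRS engine

`score = Σ_k w_k d_k + interaction`, with $d_k$ the effect-allele
dosage. A column is flipped ($x \to 2-x$) when the model's effect
allele is the array's non-counted allele; an effect allele matching
neither array allele is an error (probable strand or ID mismatch), not
a silent skip. The interaction term evaluates a ranked table of two-SNP
genotype predicates (`eq0|eq1|eq2|ge1|ge2` per SNP — covering
heterozygote-specific and carrier semantics, e.g. HLA DR3/DR4 tag-SNP
combinations); per sample the first satisfied entry contributes its
weight and the rest are ignored, so **at most one** interaction applies
per person. Missing model SNPs are a strict error by default;
`allow_missing = TRUE` scores without them (contributing 0) and warns,
matching the common situation where a reference panel lacks a couple of
the model's SNPs. Sub-part decompositions (HLA vs non-HLA, correlated
vs uncorrelated SNPs) use `snp_subset`, which restricts the linear part
and keeps only interactions entirely inside the subset.

# The synthetic-data generator

Real reference arrays cannot ship with the package, so tests run
against a Gaussian-copula world with known structure: per sample, two
independent latent $\mathcal N(0,\Sigma)$ vectors (one per chromosome)
are thresholded at $\Phi^{-1}(1-f_j)$ per SNP; the dosage is the sum of
the two indicator vectors. Choosing the copula at the *haplotype* level
means HWE holds by construction for unflagged SNPs; flagged SNPs are
overridden with exact-count columns (deliberately breaking their latent
correlation, which is documented and tested). The default world has 8
SNPs — a 4-SNP block with latent correlations 0.4–0.6, a 2-SNP block at
0.5, two independent SNPs — frequencies 0.2–0.5, $N = 2000$, seed 7. A
"case" population is created by shifting the effect-allele frequencies
of the weighted SNPs up by 0.15, a strong-effect regime chosen so
case/control AUC is comfortably away from 0.5 at $N = 2000$.

Two deliberate features of this design matter for interpreting green
tests:

* The simulator is fed the **realized** statistics of the drawn truth
  array, not the latent copula parameters. The contract under test is
  "match the statistics you were given", not "invert the copula".
  Latent correlations attenuate on the dosage scale (the 0.4–0.6 block
  realizes at roughly 0.2–0.45), which is expected copula behaviour.
* The copula world has no recombination maps, no realistic human LD
  decay, no ancestry admixture. A green end-to-end test establishes
  that the machinery matches stated statistics, not that simulated
  cohorts are indistinguishable from any particular human population.

# Known limitations

* **Systematic correlation deficit at coarse tolerance.** The optimizer
  starts from independent columns and stops the moment the loss crosses
  the tolerance, so realized correlations approach targets from below
  and retain an rms deficit of up to $\sqrt{\text{tolerance}}$ per edge
  ($\approx 0.17$ at the 0.03 default). Consequently the simulated GRS
  variance is biased low by approximately
  $2\sum_{(a,b)\in E} w_a w_b s_a s_b\,\delta_{ab}$ (with $s$ the
  column sds and $\delta$ the signed correlation deficits). In worlds
  where correlated SNPs dominate the score — such as the default test
  fixture — this bias (~7% of sd at $N=2000$) exceeds the width of a
  95% bootstrap CI of the sd, and the package's parameter-recovery
  acceptance test records exactly this: means recover, sds sit low.
  Users needing tight variance fidelity should set `tolerance` well
  below the default (e.g. 0.001), at proportionally higher cost.
* Pairwise correlations only: three-way and higher dependence is
  neither targeted nor preserved beyond what pairwise matching implies.
* No haplotype phase, no imputation, no multi-allelic variants.
* Separate-mode PCA fits are not comparable axis-by-axis between two
  arrays (components are oriented by a sign convention, but the
  subspaces themselves differ); joint mode exists for direct
  comparison.
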