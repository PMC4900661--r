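---
title: "Bayesian multi-trait analysis of half-sib trials: model, methods and design choices"
author: "mtbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multi-trait analysis of half-sib trials: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbayes)
```

## The problem

Jatropha (*Jatropha curcas* L.) breeding must improve three seed traits
simultaneously: weight of 100 seeds (W100S, g) and seed oil content
(SOC, %) upward, and phorbol ester concentration (PEC, mg/g) — the
toxicity trait — downward. mtbayes implements the full analysis chain
for a half-sib family trial of this kind: a Bayesian multi-trait mixed
model fitted by Gibbs sampling, chain diagnostics and posterior
summaries, derived genetic parameters, genetic-diversity clustering of
the estimated genotypic values, and Hazel selection indices under
configurable economic-weight scenarios. Throughout the package every
trait-dimensioned matrix uses the fixed order W100S, SOC, PEC
(`trait_set()`).

## The model

For trait $i$, family $j$ and block $k$ the phenotype is

$$y_{ijk} = \mu_i + b_{ik} + g_{ij} + e_{ijk},$$

with family (genotypic) effect vectors $g_j \sim N(0, G_0)$ iid across
families, record residual vectors $e \sim N(0, R_0)$ iid across
family-by-block records, and fixed per-trait means and block effects.
$G_0$ and $R_0$ are unstructured $3\times 3$ trait covariance matrices.
Residuals are homogeneous across observations but correlated across
traits; that is the only reading of the model under which the residual
trait covariances reported by the analysis are defined at all, so it is
the one implemented. Families are treated as unrelated (relationship
matrix $= I$); there is no pedigree or genomic-kinship support, no
plot-level nesting, and no multi-year repeated-measures structure.

Priors: an improper uniform on the fixed effects (the limit of a normal
prior with variance going to infinity), and scaled inverse-Wishart
priors $G_0 \sim W^{-1}(\Sigma_g, n)$, $R_0 \sim W^{-1}(\Sigma_e, n)$
with $n = 5$ degrees of freedom by default. The scale matrices are not
pinned by the study design, so a documented, weakly informative,
data-scaled default is used:
$\Sigma_g = \Sigma_e = 0.5\,\mathrm{diag}(\hat\sigma^2_{p})\,(n - d - 1)$,
which centres each prior on half the observed phenotypic variance
— agnostic about how variation splits between the genetic and residual
levels. Both scales are configurable, and the parameter-recovery tests
confirm that at the trial's data size (358 records per trait) the
posterior is dominated by the likelihood, not by this choice.

## The Gibbs sampler

`fit_gibbs()` cycles through exact draws from the full conditionals:

1. fixed effects $B \mid g, R_0$ — a matrix-normal draw around the OLS
   solution with covariance $R_0 \otimes (W'W)^{-1}$;
2. family effects $g_j \mid B, G_0, R_0$ — the design is complete and
   balanced by construction (incomplete tables are rejected, never
   imputed), so all families share the conditional covariance
   $(n_b R_0^{-1} + G_0^{-1})^{-1}$ and the whole $179 \times 3$ block
   is drawn in one vectorized step;
3. $G_0 \mid g \sim W^{-1}(\Sigma_g + \sum_j g_j g_j', \; n + q)$;
4. $R_0 \mid B, g \sim W^{-1}(\Sigma_e + \sum_r e_r e_r', \; n + N)$.

Location effects are updated in two blocks (fixed effects, then all
family effects) rather than as a single joint draw. For a balanced
design with flat fixed-effect priors the two-block scheme is an exact
Gibbs sampler whose mixing is practically indistinguishable from the
joint update, and it keeps every step a small dense matrix operation;
correctness is demonstrated against a conjugate closed form (the
single-trait, no-genetic-term model has an analytically known
scaled-inverse-chi-square posterior) and by parameter-recovery
experiments. Block effects are identified by a corner-point constraint:
the first block is absorbed into the per-trait intercept.

The stock chain protocol is 100,000 cycles, 40,000 burn-in, thinning
interval 10 — 6,000 retained draws. The package's own validation
experiments use 20,000 cycles with 5,000 burn-in (1,500 retained) so a
ten-replicate recovery study completes in about a minute on one core;
at the trial's size the chain mixes fast enough (effective sample sizes
in the thousands per 6,000 retained draws) that the shorter protocol
gives the same inferences to within Monte-Carlo error.

## Diagnostics and posterior summaries

`summarize_chain()` reports the posterior mean, median, mode, standard
deviation, 95% highest-posterior-density bounds, Geweke Z and effective
sample size for any scalar chain; `summary()` on a fit applies it to
every distinct covariance entry plus the per-trait heritabilities.
Numerical conventions, each chosen once and tested:

* **Geweke Z** compares the first 10% of the chain against the last 50%
  (the conventional windows), with each window's spectral density at
  frequency zero estimated by an AR fit with AIC order selection. A
  constant chain is a hard error (zero variance), not a silent zero.
* **ESS** divides the chain length by the integrated autocorrelation
  time, accumulating autocorrelations under the initial-positive-
  sequence rule (pair sums $\rho_{2m} + \rho_{2m+1}$ kept while
  positive). The estimate is capped at the chain length. The acf window
  grows geometrically until the truncation point is found, so long
  chains do not pay for lags that are never used.
* **Posterior mode** maximizes a Gaussian kernel density (Sheather–Jones
  plug-in bandwidth, 512-point grid; rule-of-thumb fallback if the
  plug-in estimator fails on degenerate data).
* **HPD interval** is the shortest contiguous window of sorted draws
  containing the requested mass — correct for the unimodal posteriors
  that variance components have here, and verified against a
  brute-force scan over every window. It is never longer than the
  equal-tailed interval at the same mass.

## Derived genetic parameters

`derive_report()` computes heritabilities
$h^2_i = \sigma^2_{g,i}/(\sigma^2_{g,i} + \sigma^2_{e,i})$, phenotypic
variances, and genotypic/phenotypic correlations in **two labelled
variants**: summaries of the per-draw values (a posterior distribution
for each derived quantity) and plug-in values from the posterior-mean
$G_0$ and $R_0$. The variants agree when the posterior is concentrated
but can differ for ratio quantities under a diffuse posterior, and
published tables of this kind do not always say which convention they
used — for the reference estimates shipped with the package the two
conventions even disagree beyond rounding for one correlation, so the
package reports both and never silently adjudicates.

## Diversity clustering

Families are clustered on their posterior-mean genotypic values
(`genotypic_value_means()`), the quantity the model actually estimates
— phenotypic values mix in residual noise and, with three-trait
heritabilities below one, blur the grouping.

* **Metric.** Squared Mahalanobis distance
  $d^2 = (g_1 - g_2)' S^{-1} (g_1 - g_2)$. Which covariance to invert
  is a genuine modelling choice; the default is the posterior-mean
  residual covariance $R_0$ (the classical within-genotype metric for
  distances between genotype means), with $G_0$ or the phenotypic sum
  selectable, because distances between *genetic* values can also be
  argued to deserve the genetic metric. The choice changes distances
  and can change the cluster count.
* **Ward agglomeration** is performed in whitened coordinates
  (multiplying by a Cholesky factor of $S^{-1}$ turns the Mahalanobis
  geometry into the Euclidean one), where Ward's minimum-variance
  objective is exact: each fusion level is the increase in total
  within-cluster SSE caused by that merge. This convention matters —
  Lance–Williams variants of Ward report heights that differ by a
  factor or a square root, which would shift the Mojena threshold — so
  the agglomerator is written directly from the centroid form of the
  Ward cost and tested for exact agreement with an exhaustive
  SSE-minimizing oracle (all candidate merges evaluated at every step)
  up to $n = 12$, and against `stats::hclust(method = "ward.D")` on
  half-squared distances at larger $n$.
* **Mojena rule.** The tree is cut immediately before the first merge
  (in agglomeration order) whose fusion level exceeds
  $\bar\alpha + \omega S_\alpha$, with $\omega = 1.25$ by default and
  $S_\alpha$ the sample ($n-1$ divisor) standard deviation of the
  fusion levels; first exceedance at step $j$ of an $n$-leaf tree gives
  $k = n - j + 1$ clusters, and no exceedance gives one cluster. The
  rule is scale-equivariant, so it does not depend on the units of the
  genotypic values.

Dendrograms export to Newick (via ape) with fusion levels as node
heights, plus delimited merge and assignment tables. The nine-cluster
partition reported for the original trial depends on the study's own
genotypic values and on metric conventions its text does not pin down;
it is therefore not a quantity the simulated pipeline asserts.

## Selection indices

For index traits $x$ (a subset of the three) and breeding goal
$H = w'g$ over all three traits, the optimal Hazel index solves
$Pb = Gw$ with $P$ the phenotypic covariance of the index traits, $G$
the genetic covariance of index with goal traits, and $C$ (in
$\sigma_H^2 = w'Cw$) the genetic covariance of the goal traits. Reported
per scenario: $\sigma_I = \sqrt{b'Pb}$, $\sigma_H$, accuracy
$R_{IH} = \sigma_I/\sigma_H$, monetary gain per generation
$\Delta G = i\,R_{IH}\,\sigma_H$, and correlated responses
$S = (i/\sigma_I)\,G'b$ in trait units per generation. Two readings had
to be fixed and are validated by reproduction of the reference results:

* economic weights stated in "monetary units per genetic standard
  deviation" convert to per-trait-unit weights as
  $w_i = m_i/\sigma_{g,i}$ (the alternative, $w_i = m_i$, does not
  reproduce the reference accuracies);
* the response formula is the division form $S = (i/\sigma_I)\,G'b$ —
  the standard correlated-response expression, and the only form that
  reproduces the reference response columns.

The goal always contains all three traits; only the index trait set
varies across the stock scenarios (SOC; SOC+W100S; all three) and
weight sets ($m$ all 1; SOC doubled; SOC 4, W100S 2, PEC 1), with
selection intensity $i = 1.75$ (top 10%). `rank_families()` scores
families by $b'x$ on posterior-mean genotypic values (a flagged
phenotype matrix can be supplied for the classical phenotype-based
usage), breaking ties by family ID, and flags the top
$\lceil 0.10\,n \rceil$ — 18 of 179.

## The simulator

`simulate_phenotypes()` generates exactly the structure the model
assumes: complete family-by-block-by-trait tables with multivariate
normal family effects and residuals. Its default configuration is the
study's: 179 families, 2 blocks, and the reference posterior-mean
covariance matrices as generating truths. Trait means and block
contrasts are not published; the defaults (60 g, 35 %, 2 mg/g, with a
small centred block contrast) are plausible trait-scale values, and
variance-component recovery is invariant to them — only the dispersion
parameters matter. One record per family-by-block cell is simulated
(the plot-mean level on which the model operates); the within-plot
plant level, multi-year records, spatial field structure, and the
study's unspecified replication adjustment of W100S means are not
emulated. Passing recovery tests therefore demonstrates correctness of
the estimation machinery under the model's own assumptions, not
robustness to field-data pathologies (outliers, missingness,
spatial trend) that real trials contain.

```{r sim-example}
ph <- simulate_phenotypes(sim_config(n_families = 40, seed = 7))
fit <- fit_gibbs(ph, n_iter = 2000, burn_in = 500, thin = 5, seed = 7)
head(summary(fit), 3)
```

## Degenerate inputs and numerical guards

Covariance inputs are checked for symmetry and positive
(semi-)definiteness, with the offending matrix named in the error;
simulation accepts semi-definite (including zero) matrices, while the
sampler's priors and the Mahalanobis metric require strict positive
definiteness (singular metrics are rejected with the condition number).
Incomplete or duplicated phenotype cells and missing values are hard
errors. Constant chains are flagged (`summarize_chain()`) or rejected
(`geweke_z()`, `effective_sample_size()`). Ties in the Mojena scan are
broken by the earliest merge; ties in family ranking by family ID.

## Known limitations

Single-chain diagnostics only (no Gelman–Rubin statistic); no missing
data; no pedigree/genomic relationships; no restricted or desired-gain
indices; clustering offers Ward only. The reference covariance values
shipped in `reference_covariances()` are rounded to three decimals, so
analyses seeded from them carry that rounding into derived quantities —
visible as small (sub-percent to a few percent) deviations in the most
cancellation-prone index responses.
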