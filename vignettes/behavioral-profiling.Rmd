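---
title: "Multidimensional behavioral profiling of stress resilience and susceptibility"
author: "StressBattery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional behavioral profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StressBattery)
```

## The problem

A rodent behavioral test battery measures each animal on many variables
across several assays — open field (OF), forced swim (FST), social
interaction (SIT), elevated plus maze (EPM), novel object recognition
(NOR), startle/prepulse inhibition (PPI), sucrose preference (SPT) and
shuttle box (SB). After an acute inescapable-shock stressor, group means
often barely move, yet individual animals differ strikingly: some become
helpless (many shuttle-box escape failures, long escape latencies), others
cope. Univariate tests on one variable at a time miss this structure.

This package implements a multivariate workflow for such data:

1. **Univariate screen** — per variable, a Student *t* or Wilcoxon rank-sum
   comparison of the shocked (IS) and non-shocked (NS) groups, routed by a
   Kolmogorov–Smirnov normality check, plus a mean-centered Levene test of
   variance equality (stress often inflates variance without moving means).
2. **Helplessness classification** — k-means on the two Z-scored shuttle-box
   escape measures, cluster number chosen by silhouette, the higher-failure
   cluster labeled H (helpless). The H/NH-by-group contingency is tested
   with a Pearson chi-squared (no continuity correction).
3. **Feature structure** — Spearman correlations among variables; Ward
   hierarchical clustering of variables; a chi-squared test of whether the
   two top clusters separate resilience- from susceptibility-related
   variables; permutation reliability by re-running the pipeline on random
   70% subsets and on column-shuffled data; common factor analysis with
   varimax rotation.
4. **Covariation patterns** — PCA by SVD with a shuffled-data null on the
   explained variances, split-data component reliability, a VIF screen for
   choosing near-independent representative variables, per-component group
   tests, and a linear discriminant classifier on cumulative PC sets with a
   shuffled-data permutation p value.
5. **Individual profiles** — Ward clustering of rats, a chi-squared scan
   across cut levels, best-of-restarts k-means with silhouette-based and
   semi-supervised cluster-number selection, per-cluster Z-profiles, and a
   cross-algorithm correspondence score.

All data live in a `BehavioralBattery`, a `SummarizedExperiment` with
variables as rows (metadata: test membership, resilience/susceptibility
valence) and rats as columns (metadata: group, helpless label).

## Key modeling choices

**Valence.** Every variable is labeled `resilience` (higher = adaptive
coping; e.g. sucrose preference, open-arm time) or `susceptibility`
(higher = stress impact; e.g. escape failures, immobility). Two variables
can be strongly associated yet have opposite signs after Z-scoring, which
motivates two distances over variables:

- plain Euclidean distance between Z-scored variable vectors (monotone in
  `1 - r`), which *keeps* sign information and is the default for the
  valence-separation analysis — a tree built this way can put positively
  covarying susceptibility variables on one side and resilience variables
  on the other;
- the sign-independent distance `min(||x - y||, ||x + y||)`, which treats a
  variable and its negation as identical and is the right tool when the
  question is *strength* of association regardless of direction — e.g.
  when asking whether variables cluster by test membership. Using it for
  the valence question would be self-defeating: it merges each variable
  with its anti-correlated partners, exactly the distinction valence
  carries. Both metrics are available in `wardLinkage()`.

**Ward linkage** uses the Lance–Williams update on squared dissimilarities
with heights reported on the dissimilarity scale (`hclust` method
`ward.D2`). For the sign-independent metric this update is applied as if
the input were Euclidean — an approximation, since that metric is not
embeddable in a Euclidean space; the cophenetic coefficient reported
alongside quantifies how well any tree represents the input distances.

**Z-scoring** pools both groups and uses the sample (n−1) standard
deviation; `zscores()` is idempotent and refuses constant columns rather
than silently producing NaNs. Missing values are rejected at load
(`readBattery(drop_incomplete = TRUE)` drops rats instead, mirroring the
practice of excluding animals rather than imputing).

**Chi-squared tests** never apply the Yates continuity correction: the
battery's worked example — the helpless-by-group table (IS: 20 H, 3 NH;
NS: 8 H, 14 NH) — gives 12.2443 uncorrected and about 10.19 corrected, and
the uncorrected Pearson statistic is the one this workflow standardizes on.

**Rank-sum convention.** `compareGroups()` reports the rank sum of the
first sample as its statistic and the Mann–Whitney U alongside, since both
conventions circulate; p values come from exact enumeration when
`min(n) <= 10` without ties, and from the tie-corrected normal
approximation with continuity correction otherwise.

**Normality routing.** The auto route uses the plain one-sample KS test of
the standardized sample against N(0,1). With fitted mean and SD this p
value is conservative (it under-rejects), which merely makes the router
prefer the *t*-test on borderline samples; the Lilliefors-corrected
variant is available (`ksNormality(..., lilliefors = TRUE)`) when the
normality test itself is the question.

**LDA.** The classifier is a two-class linear discriminant with pooled
covariance, no shrinkage, and a pseudo-inverse when the pooled covariance
is singular. Accuracy is the mean over unstratified 70/30 train/test
splits (splits are redrawn if a class is missing from training). The
comparison p value is empirical: the fraction of shuffled-data iteration
accuracies at or above the observed mean, with the usual +1 correction.
Because splits are unstratified and samples small, the null accuracy sits
slightly below 1/2 for balanced classes and near the majority rate for
imbalanced ones — the shuffled baseline, not 0.5, is the honest reference.

**Nulls are re-drawn per iteration.** Both `clusteringReliability()` and
`pcaReliability()` shuffle the data freshly inside each null iteration.
Shuffling once and resampling that single dataset would estimate the
behavior of one arbitrary null dataset (whose clustering may, by chance,
align with the labels), not the false-positive rate.

**Semi-supervised k selection.** Silhouette values often plateau; the rule
implemented is: among candidates whose mean silhouette is within
`delta = 0.02` (absolute) of the maximum, take the largest k whose
clusters-by-groups chi-squared is significant at 0.05; if none qualifies,
return an explicit no-selection. The 0.02 tolerance operationalizes
"several k look equally good" on the silhouette scale, where differences
below ~0.02 are within resampling noise at this sample size.

**Silhouettes** default to squared Euclidean distance, consistent with the
k-means objective. Singleton clusters score 1 by convention and are
flagged; exact duplicates split across clusters score 0 and are flagged.

## The synthetic generator

`generateBattery()` draws datasets with the structure the analyses assume,
so every stage is testable without animal data. For rat *i* and variable
*v* of test *t*:

$$x_{iv} = \lambda_{test}\, f_{it} + s_v\, \lambda_{sus}\, u_i + m_{c(i),v}
  + \delta_{SB}\,[H_i,\ v \in SB_{sus}] + \varepsilon_{iv}$$

- $f_{it} \sim N(0,1)$ per test: strong intra-test, weak inter-test
  correlation;
- $u_i \sim N(0,1) + \delta_H H_i$: a latent resilience–susceptibility
  axis loading on all variables with valence sign $s_v$ (+1
  susceptibility, −1 resilience); the latent helpless flag $H_i$ is drawn
  with probability 0.87 (IS) / 0.36 (NS), matching the composition of the
  reconstructed helpless-by-group table (20/23 and 8/22);
- $\delta_{SB} = 3$ SD: an extra helplessness signature on the shuttle-box
  susceptibility variables. This term emulates the clearly bimodal
  escape-failure distribution that makes the H/NH k-means nearly
  deterministic in real batteries; an axis shift alone cannot produce a
  two-variable clustering that is ~95% accurate;
- $m_{c,v}$: profile-cluster offsets (3 clusters by default: neutral,
  susceptible-like +0.8 on susceptibility variables, resilient-like) with
  group-dependent membership probabilities concentrating the
  susceptible-like cluster among shocked rats;
- $\varepsilon_{iv} \sim N(0,1)$.

Defaults are fixed at the study scale: 22 NS / 23 IS rats, 26 variables
over 8 tests. The loadings $\lambda_{test} = 1.0$, $\lambda_{sus} = 0.9$
were chosen once so that same-valence cross-test correlation (≈0.29)
exceeds opposite-valence within-test correlation (≈0.07) while intra-test
same-valence correlation stays strongest (≈0.64) — the regime in which
valence clustering can emerge despite intra-test correlations dominating,
which is the phenomenon the workflow is designed to detect. With a single
cluster and no helpless mixture, the population covariance has the closed
form $\lambda_{test}^2 B + \lambda_{sus}^2 v v' + \sigma^2 I$
(`generatorCovariance()`), which the generator is verified against.

What the generator does *not* emulate: non-Gaussian marginals (counts,
percentages, bounded indices), heteroscedastic stress effects on single
variables, test-order carryover, and missing data. Passing tests therefore
show that the *procedures* behave correctly under the assumed latent
structure, not that real batteries have that structure.

```{r generator}
sim <- generateBattery(defaultBatteryConfig(seed = 7))
sim$battery
table(sim$truth$group, sim$truth$helpless)
```

## A compact run

Problem sizes here are reduced for a quick build; `defaultRunConfig()`
defaults to the study-scale iteration counts (10^4 reliability iterations,
1000 LDA splits, 10^4 k-means restarts) and `fast = TRUE` to exploratory
ones.

```{r pipeline}
cfg <- defaultRunConfig(seed = 1, fast = TRUE)
report <- runPipeline(cfg)
report
```

```{r pieces}
# valence separation of the two top variable clusters
report$features$valence_chi2

# explained variance against the shuffled null
round(report$pca$fit$explained_pct[1:5], 2)
report$pca$null$flagged[1:5]

# LDA on cumulative PCs predicting helplessness
report$pca$lda$results
```

## Numerical conventions and degenerate inputs

- PCA components are signed so each component's largest-magnitude
  coefficient is positive; SVD signs are otherwise arbitrary and would make
  coefficient tables irreproducible across platforms. Rank-deficient input
  is allowed (trailing components report 0%).
- Split-data PC matching uses absolute correlations: a subsample can flip a
  component's sign.
- k-means restarts draw initial centroids uniformly from the observations;
  restarts that collapse to an empty cluster are re-drawn (up to 50 times)
  rather than propagated.
- Linkage tie-breaks follow `hclust`'s deterministic lowest-index rule, so
  trees are identical across platforms.
- Permutation iterations whose subsampled table degenerates (an absent
  class or cluster) count as non-significant — a conservative choice that
  can only lower the reported reliability.
- Factor extraction is maximum likelihood (`factanal`) with a
  principal-axis fallback on non-convergence; uniquenesses at the
  optimizer's bound are flagged as Heywood cases.
- Every stochastic function takes an explicit seed and restores the
  caller's RNG state; the pipeline derives independent per-stage seeds from
  one master seed with a counter scheme, so changing one stage's seed never
  perturbs another stage.

## Limitations

- The reliability fractions and cluster profiles depend on the planted
  effect sizes; on real data with weaker structure the same procedures
  report weaker numbers — the package reports, it does not guarantee.
- Ward on the sign-independent distance is an approximation (above).
- The chi-squared tests use the asymptotic distribution; with 26 variables
  split 2×2 some expected counts are small, and the permutation reliability
  machinery — not the single p value — is the intended evidence.
- No multiple-testing correction is applied across the univariate battery;
  the battery table reports raw p values by design.
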