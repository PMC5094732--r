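---
title: "Non-parametric combination of permutation tests for multi-omics data"
author: "npcombine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-parametric combination of permutation tests for multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcombine)
```

## The problem

Modern studies frequently measure several molecular layers — sequencing
counts, microarray intensities, genotypes, protein abundances — on the same
(or partially overlapping) biological samples. The scientific question is
usually conjunctive: which genes are associated with the outcome in *at
least one* layer, accumulating evidence across layers that individually may
fall short of significance? Because the layers are measured on the same
samples they are correlated, and classical meta-analysis (which assumes
independent studies) misbehaves: combining dependent p-values parametrically
inflates the type-I error, sometimes badly enough that analysing one dataset
alone would have been better.

`npcombine` implements the non-parametric combination (NPC) of dependent
permutation tests for this setting. The global null hypothesis for a feature
— "not associated with the outcome in any modality" — is split into one
partial null per modality. Each partial null is tested with a statistic
suited to its data type; the joint null distribution of all statistics is
estimated by permuting the outcome *identically across all modalities*,
which preserves the between-dataset dependence without ever modelling it;
and the partial permutation p-values are combined into a single global
statistic whose own permutation distribution yields the global p-value.

## The procedure

Let $T^i_b$ denote the statistic of modality $i$ under permutation
$b \in \{0, 1, \dots, B\}$, with $b = 0$ the observed labelling.

1. **Statistics.** For every modality and every permutation, compute the
   association statistic, oriented so that larger values mean stronger
   evidence (`computeStatistics()`).
2. **Partial (pseudo-)p-values.** Pool each feature's $B + 1$ statistics and
   compare self-inclusively:
   $\lambda^i_b = \#\{b' : T^i_{b'} \ge T^i_b\} / (B + 1)$
   (`poolPValues()`). For $b = 0$ this is the augmented estimator
   $(1 + \#\{b' \ge 1 : T^i_{b'} \ge T^i_0\})/(B+1)$: permutation p-values
   are never zero, which matters because a single zero among thousands of
   features wrecks FDR control. The same symmetric rule applied to the
   permuted rows produces the pseudo p-values $\lambda^i_b$, $b \ge 1$, and
   guarantees that observed and pseudo p-values share one distribution under
   the null — the property the combining step relies on. (Only the observed
   row's estimator is forced by the definition; extending the self-inclusive
   count to all rows is this package's reading, chosen for that symmetry.)
3. **Combination.** Per feature and per permutation index, map the vector of
   partial p-values to a global statistic (`combinePValues()`):
   Fisher $-2\sum_i w_i \log \lambda^i_b$,
   Liptak $\sum_i w_i \Phi^{-1}(1-\lambda^i_b)$,
   Tippett $\max_i w_i (1-\lambda^i_b)$. Tippett rejects as soon as any one
   partial test is strong; Liptak rewards several moderately small partial
   p-values; Fisher sits between. Optional positive weights (normalized to
   sum to 1) tilt the combination towards the more trusted modality.
4. **Global p-value.** Apply the same pooled comparison to the $B + 1$
   combined statistics (`globalPValue()`), then Benjamini–Hochberg-adjust
   globally and per modality (`runNPC()`).

Assumptions are minimal: samples exchangeable under the global null, and
partial statistics marginally valid for their own nulls. Nothing is assumed
about the dependence between modalities — that is exactly what the
synchronized permutations carry through the pipeline.

### Partially overlapping samples

The permutation plan is built over the union of all samples (the design's
sample universe); each dataset reads the permuted labels of its own samples
only. Shared samples therefore receive identical relabelings in every
permutation, preserving cross-dataset correlation, while non-shared samples
still contribute information. With fully disjoint samples the procedure
degrades gracefully into a permutation-based meta-analysis.

## Per-modality statistics

| kind           | default statistic                               |
|----------------|--------------------------------------------------|
| `counts`       | log-CPM + precision weights (voom), moderated t  |
| `continuous`   | moderated t (partial F for multiclass outcomes)  |
| `genotype`     | Cochran–Armitage trend test (scores 0/1/2)       |
| `uniform_like` | Wilcoxon rank-sum (one-sided, upward in group 2) |

The moderated t shrinks per-feature residual variances towards an
empirical-Bayes prior, $\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$,
with $(d_0, s_0^2)$ estimated by moment matching of the log variances
against a scaled-F model (via `limma::fitFDist`); at the small group sizes
typical of these designs this stabilises the denominator considerably. Count
data are first transformed to $\log_2((\text{count}+0.5)/(\text{libsize}+1)
\cdot 10^6)$ with observation-level precision weights from the mean–variance
trend (via `limma::voom`), and the linear model is then fitted by weighted
least squares. For genotypes no canonical choice is dictated by the data
type alone; the Cochran–Armitage trend test was adopted because it is the
standard dosage-association test, is permutation-compatible, and has a
closed form (the $N r^2$ identity) that vectorizes over all permutations.
Ordinary covariates (age, sex, batch indicators) enter the linear-model
statistics as adjustment columns.

Two choices deserve emphasis because they trade fidelity for speed and are
deliberate:

* **Moderation hyperparameters are estimated once**, on the observed
  labelling, and reused for all permuted relabelings. Re-estimating per
  permutation is available (`moderationPerPerm = TRUE`) but roughly
  $B$-fold slower and, in our null simulations, indistinguishable in
  calibration.
* **The voom transform and its weights are computed once**, from the
  observed design, and reused across permutations. The weights describe the
  mean–variance trend of the counts, which does not depend on the outcome
  labels under the null.

### Covariates under permutation

Permuting outcome labels while covariates stay attached to samples (the
default, `permScheme = "label"`) is exact when covariates are independent of
the outcome and a good approximation otherwise. For strong covariate
effects a Freedman–Lane scheme is provided
(`permScheme = "freedman-lane"`): residuals from the covariate-only model
are permuted and re-attached to the covariate fit, and the statistic is
recomputed against the original design. This is a documented divergence
point: the two schemes answer subtly different conditional questions, and
the label scheme is the default because it is the one that extends to the
rank and trend statistics.

## Numerical choices

* **Ties pool conservatively**: the exceedance indicator uses $\ge$, so tied
  statistics raise, never lower, p-values.
* **Statistics are rounded to 10 significant digits before pooling.**
  Relabelings that are mathematically tied — e.g. the group-swapped mirror
  of any labelling under a two-sided statistic — must pool as ties; without
  rounding, floating-point noise of order $10^{-16}$ splits them and the
  permutation p-values lose their exact enumerated values.
* **Liptak clamp**: $\lambda = 1$ (total ties) would give
  $\Phi^{-1}(0) = -\infty$; p-values are clamped symmetrically into
  $[1/(2(B+1)),\, 1 - 1/(2(B+1))]$, keeping sums finite without materially
  changing pooled ranks.
* **Zero residual variance** (perfect separation, constant features) yields
  a large sentinel statistic with the effect's sign — or 0 for constant
  features, whose partial p-value then becomes 1 through total ties.
* **Exhaustive enumeration** replaces Monte-Carlo sampling automatically
  when a dichotomous outcome admits at most $B$ distinct non-identity label
  arrangements, making small-sample p-values exact. Otherwise permutations
  are sampled uniformly with replacement, with a warning when $B$ exceeds
  the group size.
* **Uncorrected mode** (`zeroCorrection = FALSE`) reproduces the classical
  estimator for comparison purposes. Fisher and Liptak are then still
  defined internally (zero p-values map to an infinite combined statistic,
  which pools by rank; the clamp bounds Liptak), although user-level
  combination of exact zeros remains an error directing to the correction.

## Default permutation budget

`B = 1000` by default: performance of the combiners saturates around that
budget in the simulation studies, while p-value granularity $1/(B+1)$
remains fine enough for FDR work at a few thousand features. For
genome-scale analyses where individual p-values must resolve below
$10^{-3}$, `B = 10000` is the sensible working value.

## Comparison methods

For benchmarking, `runIntegration()` exposes, next to the NPC combiners and
their uncorrected variants:

* `cp` — the classical parametric combination: per-modality parametric
  p-values, $-2\sum_i \log p_i$ against $\chi^2_{2k}$. Correct under
  independence, anti-conservative under positive dependence.
* `ranksum` / `npc-ranksum` — rank features within each modality (1 =
  strongest), sum the ranks; p-values from independently drawn permutation
  plans per modality (the correlation-naive baseline) or from the shared
  synchronized plan.
* `rankprod` / `npc-rankprod` — the product of ranks; the baseline version
  uses the continuous gamma-tail approximation
  $P(\prod_i U_i \le q) = q \sum_{j<k} (-\log q)^j / j!$ with
  $q = \rho / n^k$, the NPC-wrapped version the synchronized permutation
  null.
* `benjamini` — the partial-conjunction p-value
  $\min_j ((n-u+1)/j)\, \lambda_{(u-1+j)}$; at $u = 1$ it coincides exactly
  with the minimum Benjamini–Hochberg-adjusted partial p-value.

A known limitation of the rank-product gamma approximation: it treats the
scaled ranks as continuous uniforms, and at small feature counts the
discreteness of ranks dominates — at $n = 10$, $k = 2$ the approximate
p-values deviate from the exact enumerated null by up to $\approx 0.10$.
It is a ranking-faithful baseline (the approximation is monotone in the
rank product), not a small-$n$ significance procedure.

## Evaluation tools

**Partial AUC.** Methods are scored by the area under the ROC curve
restricted to specificity $[0.9, 1]$ — the operating region of a researcher
validating only the top of the list — standardized by the McClish formula
so that 0.5 is chance and 1 is a perfect ranking. The ROC is built by
sweeping distinct p-values (ties grouped, so an all-tied ranking is the
two-point diagonal) and integrated by the trapezoid rule with linear
interpolation at the region boundary, which makes the pAUC continuous in
the scores; step integration would differ only in the third decimal.
Benchmarks repeat the full simulate-analyse-score pipeline (20 repetitions
by default), report median pAUCs, and compare the best method against each
other with a *paired* two-sided Wilcoxon signed-rank test — paired because
all methods score the identical simulated datasets within a repetition.

**Joint null criterion.** A multiple-testing procedure is only as good as
its null p-values are uniform. `doubleKS()` simulates complete-null paired
datasets (independent, or perfectly correlated to stress dependence
handling), splits the samples randomly into two equal groups, runs a method,
and applies a two-sided Kolmogorov–Smirnov test of the per-gene p-values
against Uniform(0,1); the first-level KS p-values across repetitions are
themselves KS-tested against uniformity, giving the double-KS ("dks")
p-value. Permutation p-values live on a $1/(B+1)$ grid, which makes the
continuous-uniform KS test slightly conservative; JNC runs therefore use
$B \ge 200$ so the granularity stays well below the KS resolution at the
gene counts involved. The first-level test uses the asymptotic KS
distribution, safe at $\ge 200$ p-values per repetition.

## What the simulators emulate

The generators reproduce the statistical structure of common omics data
types with known ground truth:

* `simRnaseq()` — negative-binomial counts; baseline means log-normal
  (meanlog 5, sdlog 1.5, i.e. median ≈ 150 counts), dispersions uniform in
  $[0.05, 0.5]$, deregulation as fold changes drawn log-uniformly from
  $[1/3, 1/1.5] \cup [1.5, 3]$.
* `simMicroarray()` — standard-normal noise; deregulation as an additive
  group-2 shift of magnitude Uniform(0.5, 2) with random sign.
* `simSnp()` — genotypes uniform over $\{0,1,2\}$; deregulated SNPs shift
  genotype mass in group 2 to $(1/3-\varepsilon, 1/3, 1/3+\varepsilon)$
  with $\varepsilon = 0.25$.
* `simUniform()` — Uniform(0,1) values; deregulation as a $+0.3$ location
  shift in group 2.
* `simCorrelatedPair()` — two microarray-like datasets whose
  non-deregulated rows are $(X,\ \rho X + \sqrt{1-\rho^2} Z)$, giving
  population Pearson correlation exactly $\rho$; deregulated rows share
  the same shift (they represent the same biology) but carry independent
  noise, so no correlation level is imposed on them.

The SNP and uniform effect sizes are not dictated by the data types; they
were fixed once so that single-modality power at 10 samples per group lands
in the moderate range (0.5–0.9) where integration visibly helps, and both
are arguments. Library sizes in `simRnaseq()` are equal in expectation by
default; the benchmark scenarios (`assembleScenario()`) default to 2000
genes with per-modality deregulation counts (1600, 1200, 800, 400), 400
genes deregulated everywhere, and two-group designs of 4–10 samples per
group; the correlated scenario uses two microarray datasets, 10 per group,
1000 deregulated genes common to both, and $\rho \in [0.6, 1]$. After a
seeded shuffle the deregulation sets are nested (the common block first),
so "same behaviour in all modalities" — the common block plus the
all-null genes — is a well-defined evaluation subset.

What they do **not** emulate: within-dataset gene–gene correlation (the NPC
analyses each feature independently across datasets, so it would not change
the method's behaviour, but it does make simulated false-positive counts
less variable than real ones); library-size heterogeneity and GC/length
biases of real sequencing data; linkage disequilibrium between SNPs;
missing values and batch structure. Passing calibration and power checks on
these simulators therefore validates the permutation machinery and the
combining logic, not robustness to every artefact of real data.

## Problem sizes used by the test suite

The packaged checks run reduced-scale versions of the full designs: the
joint-null-criterion suite uses 200 repetitions of 200 genes over 20
samples at $B = 200$; the correlation-robustness and integration-benefit
benchmarks use 500 genes, 10 samples per group, $B = 300$ and 5
repetitions; the exhaustive-enumeration oracle uses 30 genes with 3 vs 3
samples ($B = 19$, the full permutation group). These sizes were chosen so
the entire suite completes in a couple of minutes while every qualitative
conclusion — calibration of the NPC combiners under correlation, failure of
the parametric combination, the integration advantage on shared signal —
is still decided with comfortable margins.

## Limitations

* Missing values, imputation, and batch correction are out of scope; inputs
  must be complete matrices.
* The genotype trend and rank-sum statistics support dichotomous outcomes
  without covariates; covariate adjustment is available through the
  linear-model statistics only.
* Exhaustive enumeration is implemented for dichotomous outcomes.
* The rank-product baseline's approximate p-values are inaccurate at small
  feature counts (see above).
* Weighted least squares with per-gene voom weights falls back to a
  per-gene loop for designs with covariates; the vectorized fast path
  covers the two-group, covariate-free case that dominates permutation
  workloads.
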