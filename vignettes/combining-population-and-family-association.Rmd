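---
title: "Combining population- and family-based association tests: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining population- and family-based association tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Genetic association studies often end up with two kinds of material at the
same locus: unrelated cases and controls, and nuclear families — here,
complete case/control-parent trios.  The population-based arm measures
association between the minor-allele count and disease status; the
family-based arm measures distortion of Mendelian transmission from
heterozygous parents to affected offspring, and is robust to population
stratification because it conditions on parental genotypes.  Analysing the
two arms separately wastes information.  `popfam` implements three
single-SNP statistics that pool them, together with a synthetic
mini-exome generator and a replicate harness that reproduce the classical
evaluation design for such mixed samples: 697 unrelated subjects plus 194
trios (582 family members), a rare-skewed allele-frequency spectrum, a
liability-threshold phenotype with roughly 30% prevalence, and an
additive genetic model throughout.

## The three statistics

### Weighted combination of trio and case-control estimates (`chen_lin_test`)

The family arm fits the conditional-on-parental-genotypes (CPG)
likelihood on case trios.  Under the additive log-linear model the
relative risk per minor allele is $e^{\beta}$ and each Mendelian-
consistent case trio contributes

$$\log \frac{\tau(g_o \mid g_f, g_m)\, e^{\beta g_o}}
            {\sum_{g'} \tau(g' \mid g_f, g_m)\, e^{\beta g'}},$$

where $\tau$ is the Mendelian transmission probability.  Trios with two
homozygous parents are uninformative; the likelihood is concave, and
`fit_cpg()` maximises it by safeguarded Newton iteration (analytic score
and information, step halving, $|\beta| \le 10$, convergence at
$|\Delta\beta| < 10^{-8}$, at most 50 iterations).  One-sided
transmission patterns, where the MLE diverges, are detected up front and
flagged `degenerate` rather than chased to the cap.

The population arm is an ordinary logistic regression of affection on
allele count, fitted on the case-control subsample: all trio offspring
(affected probands *and* unaffected control offspring) plus every
unrelated subject.  Trio parents never enter this arm.

Because the probands sit in both arms, the two estimates are correlated.
The covariance is estimated by a stacked influence-function (sandwich)
cross-moment: each independent unit — a trio, or an unrelated subject —
contributes its influence value for each estimator (zero for an
estimator it does not enter), and the empirical cross-moment of the
influence pairs estimates the covariance.  A configuration switch
(`assume_independent`) zeroes it for sensitivity analysis.

A Wald pre-test compares the two estimates,
$(\hat\beta_{CPG}-\hat\beta_{CC})^2 / (se^2_{CPG}+se^2_{CC}-2\,cov)$
against $\chi^2_1$ at level $\alpha_h = 0.05$.  If it does not reject,
the combined estimate is the weighted least-squares solution
$\beta_c = W_1\hat\beta_{CPG} + W_2\hat\beta_{CC}$ with
$(W_1,W_2)' = \Sigma^{-1}\mathbf 1 / (\mathbf 1'\Sigma^{-1}\mathbf 1)$
and $se_c = (\mathbf 1'\Sigma^{-1}\mathbf 1)^{-1/2}$; the test refers
$(\beta_c/se_c)^2$ to $\chi^2_1$.  If the pre-test rejects, the package
reports the within-family (CPG-only) test and flags the SNP, preserving
per-SNP output rather than abstaining.  The weighted combination is
valid when the trio relative risk and the case-control odds ratio
estimate the same quantity — essentially a rare disease and no
stratification; see the limitations below for what happens when the
disease is common.

### PC-residual covariance test (`zhu_test`)

Principal components are computed from the standardized genotypes of all
unrelated individuals — trio parents plus the unrelated case-control
subjects; offspring are excluded from the fit and receive coordinates by
projection.  Genotypes and phenotypes are regressed on the component
scores, with coefficients estimated only on the unrelated set and applied
to everyone.  With families indexed by $i$ ($k_i$ members, $N_T$
individuals in total, unrelated subjects as singleton families), the test
statistic is the residual covariance

$$T = \frac{1}{N_T}\sum_{i=1}^{N}\sum_{j=1}^{k_i}
      \tilde y_{ij}\,\tilde g_{ij},
\qquad
\widehat{var}(T) = \frac{1}{N_T^2}\sum_{i=1}^{N}
      \Big(\sum_{j=1}^{k_i}\tilde y_{ij}\,\tilde g_{ij}\Big)^2,$$

and $T^2/\widehat{var}(T)$ is referred to $\chi^2_1$.  Summing products
within a family before squaring lets within-family correlation inflate
the variance while leaving the statistic untouched.  The published
description of this statistic is verbal rather than algebraic, so the
$1/N_T$ scaling and the family-sum-squared variance used here are a
reconstruction; any common scaling of $T$ cancels in the Wald ratio, so
the test itself is insensitive to that choice.  The same applies to the
projection rule for offspring coordinates, on which the description is
silent (a midparent-score alternative gives nearly identical scores in
unstructured data).

### GEE-style score test (`zhang_test`)

The score decomposes over two mutually exclusive sets, with traits
treated as constants.  Over unrelated subjects,

$$U = \sum_i (y_i - \mu_{y,i})(g_i - \mu_{g,i}),$$

where $\mu_{y,i}, \mu_{g,i}$ are fitted values of regressions on the PC
scores (sample means when $L = 0$).  Over trio offspring,

$$R = \sum_{ij} (y_{ij} - \hat\mu_y)(g_{ij} - e_{g,i}),$$

where $e_{g,i}$ is the Mendelian expectation $(g_{im} + g_{if})/2$ formed
from PC-adjusted parental genotypes, and the offspring variance is the
exact transmission variance
$v_{g,i} = (1\{g_{im}=1\} + 1\{g_{if}=1\})/4$.  The variance of
$Z = U + R$ adds $\sum (y_i-\mu_{y,i})^2 \hat\sigma^2_g$ over unrelateds
($\hat\sigma^2_g$ the residual genotype variance of the unrelated set)
and $\sum (y_{ij}-\hat\mu_y)^2 v_{g,i}$ over offspring, and
$Z^2/var(Z)$ is referred to $\chi^2_1$.  As with the residual-covariance
test, the source description is verbal; the decomposition above is a
reconstruction validated by its reduction identities (it collapses to
the classical covariance score test without trios, and to the TDT
$\,(b-c)^2/(b+c)$ on Aa×aa trios) and by calibration under the null.
Because $E[g_{ij} \mid g_{im}, g_{if}] = e_{g,i}$ regardless of
population structure, $R$ is conditionally centered and the family
component is stratification-robust by construction.

Two choices here were genuinely open.  Offspring trait centering uses
the mean phenotype of the unrelated subjects (falling back to the
founder mean in designs without unrelateds); the alternative — the
overall sample mean — changes nothing structurally because the statistic
is invariant to affine recoding of the trait.  And the parental PC
adjustment subtracts only the PC-slope component of the genotype (no
intercept), so that with $L = 0$ it is exactly the identity and the
offspring expectation is exactly the raw Mendelian mean; any constant
shift of both parents would cancel in $g_{ij} - e_{g,i}$ anyway.
Trios with a missing parental genotype at a SNP are excluded at that SNP;
reconstructing moments for missing parents is out of scope.

## The synthetic mini-exome

The generator emulates the statistical structure of mini-exome
evaluation data; it makes no attempt to reproduce any particular
real panel's sites, linkage disequilibrium, or gene architecture.

* **MAF spectrum.** `rare_skewed` draws 70% of SNPs log-uniformly on
  $[2\times10^{-4}, 0.01]$ and 30% on $[0.01, 0.5]$.  The majority of
  SNPs are rare (MAF < 0.01) and frequencies reach the singleton level
  (about $7\times10^{-4}$ at 697 diploid founders), matching the
  rare-dominated character of exome panels.  `uniform` and `fixed_list`
  spectra serve targeted experiments.
* **Genotypes.** Founders are Hardy-Weinberg draws, independent across
  SNPs (no LD — the tests are single-SNP); offspring receive one
  uniformly chosen allele per parent.  Within-SNP family correlation is
  therefore exact, between-SNP correlation absent.
* **Phenotype.** Liability $\ell = \sum_j \beta_j g_j + \epsilon$,
  $\epsilon \sim N(0,1)$, affected when $\ell$ exceeds a threshold
  calibrated as the empirical $(1-K)$-quantile of liability in a
  100,000-individual probe cohort.  The default target prevalence is
  $K = 0.32$: the emulated disease is decidedly common (prevalence well
  above 30%), which is exactly the regime that strains the rare-disease
  assumption of the weighted-combination method.  The default causal
  architecture marks 2% of SNPs causal with liability effects uniform on
  $[0.1, 1.4]$, the moderate-to-strong range typical of rare-variant
  liability models.
* **Design.** Defaults are 697 unrelated subjects and 194 trios.  Trio
  ascertainment defaults to `mixed` with a 1:1 case:control offspring
  ratio (both case and control trios are analysed; control offspring
  join the case-control arm); `offspring_affected` and `random` are
  available.  Unrelated subjects are a random population draw by
  default, or ascertained to a configured case fraction.
* **Replicates.** With `fixed_genotypes = TRUE` (default) the genotype
  pool is a deterministic function of the master seed and only
  phenotypes are redrawn per replicate, mirroring workshop-style
  replicate designs; per-replicate substreams are derived from the
  master seed so any replicate is reproducible in isolation.
* **Stratification (off by default).** Two subpopulations with
  Balding-Nichols allele-frequency divergence at a configurable $F_{st}$
  and a liability offset for the second subpopulation, used only for
  robustness experiments; the primary evaluation design is homogeneous.

Passing tests on these data demonstrate calibration and power behaviour
under clean HWE founders, no LD, no genotyping error, and an exactly
additive liability.  They do not certify behaviour under LD between
test SNPs, genotype error, non-additive architectures, or real-panel
site spectra.

## Numerical and policy choices

* MAF is computed on founders only (parents + unrelateds), so
  transmitted alleles are not double-counted; MAF classes default to
  rare < 0.01 ≤ moderate ≤ 0.05 < common.
* Genotype standardization for the PC basis uses
  $\sqrt{2\hat p(1-\hat p)}$; monomorphic columns are dropped from the
  basis and from projection identically.  Component signs are fixed by
  a largest-loading-positive convention; $L$ defaults to 10.
* Missing genotypes are handled complete-case per marker; a trio with
  any missing member at a SNP leaves that SNP's family terms.  A SNP
  showing a Mendelian inconsistency in a trio drops that trio at that
  SNP only.
* Degenerate situations (monomorphic SNPs, single-class phenotype,
  separation, no informative trios, zero variance) are flagged in a
  `status` column, never raised as errors mid-scan; the evaluation
  summaries count them as non-rejections by default (conservative) and
  report their number.
* All three statistics are referred to $\chi^2_1$; p-values are
  two-sided by construction.

## Evaluation harness and problem sizes

`run_experiment()` runs every requested method on every SNP per
replicate and collects p-values; `rejection_rates()`,
`power_by_strata()` and `top_snp_table()` produce the standard
summaries (noncausal vs causal rejection rates with an optional
exclusion list, per-SNP power by MAF class and effect size, and a
best-method comparison restricted to SNPs with at least modest power,
default 0.2).  No multiple-testing adjustment is applied: comparisons
between methods are at a fixed nominal 5% level by design.

The package's own verification uses desk-scale problem sizes chosen to
give stable Monte-Carlo estimates: null calibration on the full
697 + 194 design with 2,000 rare-skewed SNPs and phenotypes redrawn
until every method has at least 2,000 valid SNP-tests; prevalence
checked on a 100,000-individual cohort; power curves from 200
replicates per effect size at a single moderately rare SNP; and
stratification robustness from three replicates of a 300-SNP,
two-subpopulation design.

## Known limitations

* **Non-monotone power of the weighted combination under a common
  disease.**  With ~32% prevalence the trio log relative risk and the
  case-control log odds ratio are genuinely different parameters at
  large effects.  The homogeneity pre-test then rejects often —
  correctly — and the method falls back to the CPG-only test, whose
  power at a rare-to-moderate MAF with ~50 case trios is near zero.
  Empirically the combination's power *decreases* from moderate to
  large liability effects while the other two methods keep rising.
  This is inherent to pre-test estimators when the homogeneity
  assumption fails, not a numerical artifact; at small effects the
  pre-test rarely rejects and the combination behaves as intended.
* Only complete trios and unrelated subjects are supported; general
  pedigrees, missing-parent reconstruction, X-linked markers, and
  covariates are out of scope.
* The family-robust variance of the residual-covariance test is a
  family-level empirical second moment; with very few families it is
  noisy, and for extremely rare variants (one carrier family) the Wald
  ratio cannot exceed 1, making the test conservative in exactly the
  regime where rare-variant methods are needed.
* The exact published algebra of the residual-covariance and GEE score
  statistics is not available in the source text; both are
  reconstructions validated by reduction identities and calibration,
  as described above.
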