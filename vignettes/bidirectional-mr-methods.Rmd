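---
title: "Methods: bidirectional two-sample Mendelian randomization with bidirMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample Mendelian randomization with bidirMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirMR)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with the variant–exposure and variant–outcome associations taken from two
independent GWAS. For variant $k$, let $\hat\beta_{Xk}$ and $\hat\beta_{Yk}$
be the estimated per-allele effects (log odds ratios) with standard errors
$\hat\sigma_{Xk}$, $\hat\sigma_{Yk}$. A variant is a valid instrument when it
is (i) associated with the exposure, (ii) independent of confounders, and
(iii) affects the outcome only through the exposure. Under those assumptions
each variant yields a Wald ratio $\hat\theta_k = \hat\beta_{Yk} /
\hat\beta_{Xk}$ with first-order standard error $\hat\sigma_{Yk} /
|\hat\beta_{Xk}|$, and the inverse-variance weighted (IVW) estimator pools
them:

$$\hat\theta_{\mathrm{IVW}}
  = \frac{\sum_k \hat\beta_{Xk}\hat\beta_{Yk}\hat\sigma_{Yk}^{-2}}
         {\sum_k \hat\beta_{Xk}^2\hat\sigma_{Yk}^{-2}},
\qquad
\hat\sigma_{\mathrm{IVW}} =
  \sqrt{1 \Big/ \sum_k \hat\beta_{Xk}^2\hat\sigma_{Yk}^{-2}}.$$

This is weighted least squares of $\hat\beta_{Yk}$ on $\hat\beta_{Xk}$
through the origin, and it is the package's primary estimator. The
fixed-effect variance above is the default (`mrIVW(..., model = "fixed")`)
because it is the form the pooled standard error printed above actually
implements; a multiplicative random-effects variant inflating the standard
error by $\sqrt{\max(1, Q/(k-1))}$ is provided for cross-checking against
tools that default to it. Both models share the point estimate.

Exclusion-restriction violations (horizontal pleiotropy) bias IVW, so three
complementary estimators with weaker assumptions are included:

* **MR-Egger** (`mrEgger`): weighted regression of $\hat\beta_{Yk}$ on
  $\hat\beta_{Xk}$ with a free intercept. The slope estimates the causal
  effect under the InSIDE assumption (direct effects uncorrelated with
  instrument strength); the intercept estimates the average direct effect and
  tests for directional pleiotropy. Instruments are first oriented so every
  $\hat\beta_{Xk} > 0$ (flipping both betas together), which the regression
  needs to be invariant to arbitrary allele orientation.
* **Weighted median** (`weightedMedian`): the ratio at cumulative weight
  percentile 0.5, with weights $\hat\beta_{Xk}^2 / \hat\sigma_{Yk}^{2}$
  normalized and the percentile of the $j$-th sorted ratio taken as
  $(S_j - w_j/2)/S$, linearly interpolated. It is consistent when instruments
  carrying more than half the weight are valid. Its standard error comes from
  a parametric bootstrap (default 1000 draws, seeded and recorded).
* **MR-PRESSO** (`mrPresso`): a simulation-based global pleiotropy test with
  per-variant outlier detection and outlier-corrected re-estimation,
  described below.

## Instrument selection and harmonization

Selection (`filterVariants`, `excludePalindromes`, `ldClump`, `findProxy`)
follows the conventional QC chain for summary-level instruments:

* significance at a configurable threshold (genome-wide $5\times10^{-8}$ for
  a well-powered exposure GWAS; suggestive $5\times10^{-6}$ where no variant
  reaches genome-wide significance). Thresholds are applied inclusively
  ($p \le p_{\max}$): selection semantics are kept boundary-inclusive and
  configurable.
* minor allele frequency $\ge$ 1% and Hardy–Weinberg $p \ge 10^{-4}$. Both
  rules operate on provided columns; when a record lacks the column the rule
  is skipped and logged rather than failed, because shared summary deposits
  often strip these fields.
* palindromic variants (A/T, C/G) with MAF above 0.45 are excluded outright —
  at such frequencies neither allele labels nor frequencies can resolve the
  strand.
* greedy LD clumping: visit variants by ascending p-value and drop any
  variant within 1 Mb (closed interval, same chromosome) of an accepted one
  at $r^2 > 0.01$. Ties on p-value break by (chromosome, position), making
  the output independent of input row order.
* instruments missing from the outcome dataset may be replaced by a proxy in
  LD at $r^2 > 0.8$ (strict), provided the proxy has its own exposure record.

Instrument strength is summarized by the variance explained
$2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ and the F-statistic
$R^2(N-2)/(1-R^2)$, with $F < 10$ flagging a weak instrument. The $N$ used
should be the sample size of the dataset actually analyzed, not a larger
discovery meta-analysis.

Harmonization (`harmonizePair`, `harmonizeSets`) puts both studies on a
common effect allele: identical orientations pass through; swapped alleles
flip the outcome beta's sign; complementary alleles are strand-flipped first.
Magnitudes of effects and standard errors are never altered. Palindromes are
dropped by default — the outcome deposit may carry no allele frequencies, and
high-MAF palindromes were already excluded at selection, so residual cases
are rare and not worth an unverifiable guess. The alternative
`infer_by_frequency` policy aligns by frequency concordance and refuses to
guess when both frequencies sit within 0.08 of 0.5; that window is
deliberately conservative relative to the 0.45 selection cutoff.

## Heterogeneity and pleiotropy diagnostics

Cochran's $Q = \sum_k w_k(\hat\theta_k - \hat\theta_{\mathrm{IVW}})^2$ uses
the same first-order weights $w_k = \hat\beta_{Xk}^2/\hat\sigma_{Yk}^2$ as
the fixed-effect IVW, so $Q/(k-1)$ is exactly the multiplicative
random-effects inflation factor — the two modules stay mutually consistent.
The p-value is the $\chi^2_{k-1}$ upper tail.

MR-PRESSO computes, for each variant $j$, the leave-one-out IVW slope
$\hat\theta_{(-j)}$ and the observed residual sum
$\mathrm{RSS}_{\mathrm{obs}} = \sum_j \hat\sigma_{Yj}^{-2}
(\hat\beta_{Yj} - \hat\theta_{(-j)}\hat\beta_{Xj})^2$. The null distribution
comes from parametric replicates $\beta^*_{Xj} \sim N(\hat\beta_{Xj},
\hat\sigma_{Xj}^2)$, $\beta^*_{Yj} \sim N(\hat\theta_{(-j)}\hat\beta_{Xj},
\hat\sigma_{Yj}^2)$, re-scoring each replicate with its own leave-one-out
slopes. Empirical p-values use the add-one estimator $(1 + \#\{x^* \ge
x\})/(1 + n_{\mathrm{sim}})$, so they are never zero and are bit-reproducible
given a seed. Per-variant outlier tests are Bonferroni-corrected at
$\alpha/k$. When outliers are found the corrected estimate is IVW on the
remaining variants, and a distortion p-value is obtained by bootstrapping the
corrected-minus-raw difference (resampling subsets of the full set at the
corrected size, reps equal to `nSim`); this bootstrap formulation of the
distortion test is the package's own documented convention. The default
`nSim` is 1000; 10000 is recommended when the global p-value is a headline
number, since its Monte-Carlo error is
$\approx\sqrt{p(1-p)/n_{\mathrm{sim}}}$.

Leave-one-out estimates and funnel data (ratio vs precision
$|\hat\beta_{Xk}|/\hat\sigma_{Yk}$) are emitted as tables; rendering is left
to the user's plotting layer.

## Power

For a binary outcome the package uses the normal-approximation
non-centrality $z = |\ln \mathrm{OR}| \sqrt{N R^2 K(1-K)}$ (outcome sample
size $N$, case fraction $K$, instrument variance explained $R^2$), giving
two-sided power $\Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})$.
`detectableORInterval` inverts this by root-finding on the log-OR scale
(bisection via `uniroot`, tolerance $10^{-12}$; the returned bounds reproduce
the target power to well under $10^{-6}$). The interval between the two
bounds is the underpowered zone of the design. Power is exactly $\alpha$ at
OR = 1 and symmetric in OR vs 1/OR.

## The synthetic generator: what it emulates and what it does not

`simulateTwoSample` generates summary statistics directly at the summary
level — no individual genotypes — which is sufficient for every estimator
here and standard practice for two-sample MR simulation. Per variant:
$\gamma_k \sim N(\mu_\gamma, \sigma_\gamma^2)$ (true exposure effects),
direct effects $\alpha_k$ with configurable mean (directional pleiotropy),
spread (balanced pleiotropy) and correlation with $\gamma_k$ (InSIDE
violation, implemented as $\alpha_k = \mu_\alpha + \tau(\rho z_{\gamma k} +
\sqrt{1-\rho^2}\,\varepsilon_k)$), total outcome effects $\Gamma_k = \theta
\gamma_k + \alpha_k$, and observed effects drawn around the truths with
uniformly sampled standard errors. p-values are computed from beta/se so the
selection filters behave as they would on real tables.

Defaults are fixed to the study design the package was built around: 13
instruments; exposure effects near 0.12 on the log-odds scale with standard
errors of 0.016–0.022, putting per-variant F-statistics in the 30–60 range
typical of genome-wide significant hits from a ~25,000-sample case-control
GWAS; outcome standard errors of 0.025–0.045 as seen for suggestive-level
signals in a ~35,000-sample GWAS; allele frequencies uniform on (0.1, 0.9);
non-palindromic alleles; one locus per variant. `simulateLdLocus` adds
LD-structured toy loci ($r^2 = e^{-\mathrm{decay}\cdot d_{\mathrm{kb}}}$)
for the clumping rules.

Two calibration choices deserve a note. The parameter-recovery runs in the
test suite use deliberately strong instruments (exposure $z \approx 15$–30,
$F$ in the hundreds): the first-order Wald ratio ignores $\hat\sigma_{Xk}$
and therefore attenuates estimates by a factor of roughly $1/(1+1/F)$, a
known property of the estimator rather than a bug, and at $F \approx 40$ that
attenuation would be comparable to the Monte-Carlo resolution of a
500-replicate run. Strong instruments keep the check about correctness of the
implementation. Likewise the Egger-intercept recovery run sets $\theta = 0$
so that slope dilution cannot leak into the intercept being checked.

What the generator does *not* emulate: realistic LD from population panels,
liability-scale case-control genetics, winner's curse and selection bias in
the exposure GWAS, sample overlap between the two studies, or
ancestry-stratified frequency differences. Passing tests therefore certify
the estimators, filters and plumbing — not robustness of MR itself to those
real-data phenomena.

## Numerical and reporting conventions

* Betas are always log odds ratios internally; odds ratios are derived views
  (`oddsRatio`), never stored.
* Every 95% interval uses the fixed 1.96 normal multiplier. MR-Egger
  p-values use the $t_{k-2}$ distribution while keeping the 1.96 interval;
  exactness is traded for cross-method comparability, and both the inflation
  factor and df are recorded in the estimate's `extras`.
* Egger and both IVW standard errors never deflate: residual inflation
  factors are floored at 1.
* All empirical p-values use the add-one rule; all stochastic routines take
  an explicit seed and restore the caller's RNG state.
* Written report tables round-trip numerics exactly (17 significant digits).
* Degenerate inputs fail loudly: ratio estimators refuse $\hat\beta_{Xk} =
  0$, MR-Egger and the weighted median need $\ge 3$ instruments, MR-PRESSO
  $\ge 4$, and an emptied selection stage aborts the pipeline naming the
  stage.

## Pipeline and multiplicity

`runDirection` chains selection → harmonization → estimation → diagnostics →
power for one direction, logging in/out counts at every stage so instrument
attrition is auditable. `runBidirectional` runs both directions with
direction-specific selection thresholds and flags each primary (fixed-effect
IVW) p-value against the Bonferroni threshold $\alpha/2$ (0.025 by default
for two association tests). Identical configuration and seed reproduce every
number bit-for-bit.

## Problem sizes used by the test suite

The shipped tests calibrate the type-I error on 1000 null replicates of a
13-instrument study, parameter recovery on 500 replicates, PRESSO null
behaviour on 100–200 replicates at 300–500 simulations each, and outlier
correction on 100 replicates — sizes at which the binomial/Monte-Carlo
resolution of each check is several times finer than the tolerance being
asserted.

```{r}
sim <- simulateTwoSample(nSnp = 13, theta = 0.25, seed = 42)
runDirection(sim$exposure, sim$outcome, seed = 7,
             kCasesOutcome = 12289 / 34615)
```
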