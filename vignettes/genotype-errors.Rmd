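---
title: "Geometric rare-variant tests under genotype misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric rare-variant tests under genotype misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvgeom)
library(dplyr)
```

## The model

Gene-based rare-variant tests aggregate association evidence across the $m$
variant sites of a gene. Writing $c^+_i$ and $c^-_i$ for the minor-allele
counts at site $i$ among $N^+$ cases and $N^-$ controls, most published tests
are members of one of two geometric families:

* **length (burden-style) tests**
  $L_p = \big(\sum_i |c^+_i/2N^+|^p\big)^{1/p} -
  \big(\sum_i |c^-_i/2N^-|^p\big)^{1/p}$, which compare the sizes of the two
  frequency vectors, and
* **joint (variance-component-style) tests**
  $J_p = \big(\sum_i |D_i|^p\big)^{1/p}$ with
  $D_i = c^+_i/2N^+ - c^-_i/2N^-$, which also respond to the angle between
  them.

Under a binomial sampling model, $c^\pm_i \sim \mathrm{Bin}(2N^\pm, f^\pm_i)$,
so $D_i$ has mean $\mu_{D_i} = f^+_i - f^-_i$ and variance
$\sigma^2_{D_i} = f^+_i(1-f^+_i)/2N^+ + f^-_i(1-f^-_i)/2N^-$
(`diff_moments()`). The variance-scaled joint statistic
$J^2_{2,\mathrm{scaled}} = \sum_i (D_i/\sigma_{D_i})^2$ (`scaled_joint2()`)
is asymptotically $\chi^2_m$ under the null and noncentral $\chi^2_{m,\lambda}$
with $\lambda = \sum_i (\mu_{D_i}/\sigma_{D_i})^2$ under the alternative; it
acts as a frequency-weighted joint test.

Genotype misclassification enters at the allele level: a major allele is
read as minor with probability $\varepsilon_{01}$ and a minor allele as major
with probability $\varepsilon_{10}$, independently per allele, so the
observed MAF is $f^* = f(1-\varepsilon_{10}) + (1-f)\varepsilon_{01}$
(`perturbed_maf()`). Two regimes matter:

* **non-differential** errors (equal rates in cases and controls) leave the
  null intact ($f^{+*} = f^{-*}$ whenever $f^+ = f^-$) but shrink every
  alternative mean by exactly $1-\varepsilon_{10}-\varepsilon_{01}$
  (`mean_shrinkage()`) while inflating the variance whenever
  $\varepsilon_{01} > \varepsilon_{10} f/(1-f)$ — for rare variants,
  essentially always. Both effects cost power, and the
  $\varepsilon_{01}$ channel dominates because almost every subject is a
  common homozygote: at MAF 0.1% in 10,000 individuals, a 1%
  $\varepsilon_{01}$ produces on the order of a hundred spurious minor
  alleles while a 10% $\varepsilon_{10}$ removes about one
  (`expected_misclassifications()`).
* **differential** errors (rates that depend on phenotype) shift the null
  mean to
  $f((\varepsilon^-_{10}-\varepsilon^+_{10}) +
  (\varepsilon^-_{01}-\varepsilon^+_{01})) +
  (\varepsilon^+_{01}-\varepsilon^-_{01}) \ne 0$
  and therefore inflate the type-I error of any test calibrated without
  them.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws control genotypes from Hardy-Weinberg equilibrium
at the population MAF and case genotypes from HWE at
`case_maf(f, RR) = f\,RR / (1 + f(RR-1))`, the standard
multiplicative-per-allele map under the rare-disease approximation. The map
is our own choice where only relative risks are stated: it is the identity at
$RR = 1$, keeps frequencies in $(0,1)$, and pairs protective risks $1/r$
with their reciprocals exactly. Sites are independent — the framework's
no-LD assumption — and errors are applied afterwards as independent
per-allele Bernoulli flips with each group's own rates. Consequently a
common-homozygote becomes a heterozygote at rate
$2\varepsilon_{01}(1-\varepsilon_{01})$, and rare-homozygote errors arise
only as double flips; there is no separate genotype-level error channel, no
read-depth model, no population structure, and no LD. Passing tests
therefore demonstrate correctness of the error mechanism and sampling model,
not robustness to haplotype structure or caller-specific error profiles in
real sequence data.

The default study conditions are fixed by the three grid constructors:
1000 cases, 1000 controls and $m = 8$ sites throughout;
seven $(\varepsilon_{01}, \varepsilon_{10})$ settings
$(0,0), (0,0.1), (0,0.5), (0.01,0), (0.05,0), (0.01,0.1), (0.05,0.5)$ —
$\varepsilon_{10}$ an order of magnitude larger than $\varepsilon_{01}$,
reflecting the difficulty of calling rare minor alleles; five MAF
configurations (all 1%, all 0.1%, all 0.01%, and two mixed settings with a
quarter of sites at 1%); and six causal mixes for the non-differential grid
(210 settings, 35 of them null), four case:control rate ratios
(1.2, 1.5, 1/1.2, 1/1.5) for the differential grid (140 settings, all null,
the ratio applied to both error channels), and a single-causal-variant
follow-up grid at 8 and 16 sites (70 settings). Where the enumeration needed
a convention the conditions do not pin down, we fixed one and use it
everywhere: sites are ordered by decreasing MAF; causal statuses are
assigned from the largest-MAF site down (risk-increasing before
risk-reducing before non-causal); each site's relative risk follows its own
MAF (1% → 1.5, 0.1% → 3, 0.01% → 5, reciprocals for protective sites).

## Permutation inference

`permutation_pvalue()` recomputes a statistic under random phenotype
relabellings preserving $N^+$ and $N^-$. The default tie rule counts
permuted values **greater than or equal to** the observed one: it is
conservative, can never return 0, and reproduces the deflation seen at
ultra-rare MAF, where the permutation distribution is so discrete that the
achievable level falls below the nominal 5%. The strictly-greater rule is
available; no $+1$/(B+1) smoothing is applied, matching the plain
proportion estimator. Only carriers can change a count under relabelling,
so the engine assigns each carrier a uniform rank among all $N$ individuals
and sums dosages of carriers ranked inside the case block — cost scales
with the number of carriers, not the cohort, which is what makes the
grid-scale runs tractable on one CPU.

For the infinity norm the joint statistic is taken as the **maximum signed
difference** $\max_i D_i$: the test as used is one-sided, looking for an
excess of minor alleles in cases, and the signed maximum is the value the
index-of-largest-difference formulation clearly intends. An option
(`absolute = TRUE`) switches to $\max_i |D_i|$ for designs where protective
variants are expected to carry the signal. Norm 8 is exposed alongside
$\infty$ because both appear in common summaries of the eight-test panel.

## Asymptotic calculators and their conventions

`l1_power()` computes normal-approximation power with critical value
$C = z_{1-\alpha}\sqrt{\sum_i \sigma^2_{D_i,H_0}}$ and
$\pi = 1-\Phi\!\big((C - \sum_i \mu^*_{D_i})/\sqrt{\sum_i \sigma^{*2}_{D_i}}\big)$;
`l1_sample_size()` inverts it in closed form using
$t^*_i = \tfrac12\big(f^{+*}_i(1-f^{+*}_i) + f^{-*}_i(1-f^{-*}_i)/k\big)$
with $k = N^-/N^+$ held fixed, so $\sigma^{*2}_{D_i} = t^*_i/N^+$.
`j2_power()` and `j2_sample_size_ratio()` do the same through the
noncentral-$\chi^2$ route, where the sample-size ratio reduces to
$\sum_i(\mu^2_i/t_i) \big/ \sum_i(\mu^{*2}_i/t^*_i)$.

One convention was genuinely open: **which null variance calibrates $C$**.
A permutation test applied to contaminated data calibrates itself against
the contaminated null, and the closed-form sample-size derivation uses the
starred $t^*_{i,H_0}$; only that choice makes `l1_power()` and
`l1_sample_size()` exact inverses and makes the predictions track
permutation-based empirical power at non-trivial error rates. The power and
sample-size calculators therefore default to `null_variance = "perturbed"`
(error-perturbed null frequencies), with `"clean"` available. The type-I
inflation calculators answer a different question — what level an analyst
realises when they trust an **error-free** calibration — so
`l1_inflated_alpha()` defaults to the clean-null $C$ with the starred null
moments in the body; under that convention non-differential errors leave a
small variance-mismatch residual, which vanishes under
`null_variance = "perturbed"` (and for permutation tests in practice).
`j2_inflated_alpha()` has no such ambiguity because the $\chi^2$ critical
value does not involve the variance.

Numerical choices: all arithmetic is in double precision directly on allele
counts; noncentral $\chi^2$ tails use R's `pchisq(..., ncp)`, accurate far
beyond the $\lambda \le 10^4$ range used here; sample sizes are reported
both continuous and rounded up. The normal approximation is not gated, but
every calculator warns when any expected minor-allele count $2Nf^*$ falls
below 5 — exactly the regime (aggregate MAF of order 0.01%) where
predictions are known to degrade. Degenerate inputs signal explicit errors:
monomorphic sites are rejected by `scaled_joint2()` (they carry no
information for the scaled statistic, though they harmlessly contribute
zero to the unscaled families), fully cancelled designs
($\sum\mu^* = 0$) make sample sizes infeasible, and `empirical_rate()`
propagates simulator validation.

## Worked example

A single site with control MAF 0.1%, case MAF 0.3%, 1000 cases and 1000
controls:

```{r reference}
d <- design_spec(0.001, f_case = 0.003, n_cases = 1000, target_power = 0.8)
suppressWarnings(l1_power(d)$power)
suppressWarnings(j2_power(d)$power)
l1_sample_size(d)$n_cases
```

The warning is the low-count contract: expected counts of 2 and 6 alleles
are thin ice for a normal approximation, and an exact binomial Monte-Carlo
puts the L1 rejection rate near 0.56 rather than 0.60 purely through
lattice effects. Differential errors on a null site are more dramatic:

```{r differential}
dn <- design_spec(0.001, eps01_case = 0.012, eps01_control = 0.010)
l1_inflated_alpha(dn)$alpha_star
```

A 20% relative difference in a 1% major-to-minor error rate turns a nominal
5% test into one rejecting more than half the time — the arithmetic behind
the caution against mixing freshly sequenced cases with database controls.

## Scale of the validation runs

The test suite validates the permutation machinery at the study's own
sample sizes (1000 + 1000, $m = 8$) with 1000 simulated cohorts and 500
permutations per cohort for type-I control, and 500 cohorts for the
analytic-versus-empirical power comparison; these sizes give binomial
Monte-Carlo standard errors of 0.7–2 percentage points, small against the
3–7% acceptance band and the 10-point agreement margin, while keeping the
full suite comfortably within a desktop run. Distributional checks
(Hardy-Weinberg proportions, binomial moments, error-flip rates) use
$2\times10^4$ to $2\times10^5$ draws and 4-standard-error bands throughout.

## Known limitations

* No LD, covariates, population structure, or read-level error model; the
  error rates are free parameters, not calibrated to any particular caller.
* Asymptotic formulas exist only for $L_1$ and scaled $J_2$; other norms
  are served by permutation alone.
* Predictions at aggregate MAF $\lesssim 0.01\%$ are flagged, not fixed:
  the discrete permutation distribution deflates the realised level and
  the normal approximation overstates power there.
* The meta-regression summaries (`summarize_grid()`) describe simulation
  output linearly; they are descriptive, not a causal model of test
  behaviour.
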