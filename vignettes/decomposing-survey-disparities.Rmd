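---
title: "Decomposing two-group disparities in survey-measured binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing two-group disparities in survey-measured binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svygap)
library(dplyr)
```

## The problem

Large household surveys such as the Demographic and Health Surveys (DHS)
routinely show that urban women are far more likely than rural women to
deliver by caesarean section. The policy question is not whether the gap
exists but *why*: how much of it reflects differences in who lives where
(wealth, antenatal-care use, parity, education, insurance coverage), and
how much reflects differences in how those characteristics translate into
outcomes? `svygap` answers this with a multivariate non-linear
decomposition of the prevalence gap, wrapped in the design-based
descriptive and regression machinery such an analysis needs around it.

All estimators in the package are weight-aware and respect a stratified
two-stage sampling design: observations carry sampling weights and are
nested in primary sampling units (PSUs, clusters) within design strata.

## The decomposition model

Write $F$ for the standard logistic function and fit a separate
survey-weighted logit in each residence group $g \in \{A, B\}$ (by
convention $A$ = urban, the comparison group; $B$ = rural, the
reference):

$$\Pr(Y_i = 1 \mid x_i, g) = F(x_i^\top \beta_g).$$

Let $\bar P_g$ be the design-weighted mean outcome of group $g$ and

$$Q = \frac{\sum_{i \in B} w_i\, F(x_i^\top \beta_A)}{\sum_{i \in B} w_i}$$

the counterfactual mean the reference group would attain under the
comparison group's coefficients. The gap splits as

$$D = \bar P_A - \bar P_B = \underbrace{(\bar P_A - Q)}_{E,\ \text{characteristics}}
    + \underbrace{(Q - \bar P_B)}_{C,\ \text{coefficients}}.$$

Because both models are canonical-link logits with intercepts, the
weighted mean of fitted probabilities equals the weighted outcome
prevalence in each group (the score identity), so $D$ is the *observed*
weighted gap, not a model artifact. `svy_decompose()` asserts
$E + C = D$ to $10^{-10}$ on every run.

### Detailed contributions

Per-category contributions use first-moment (means-based) weight shares:
with $\bar x_{gk}$ the design-weighted mean of design column $k$ in group
$g$,

$$e_k = E \cdot \frac{(\bar x_{Ak} - \bar x_{Bk})\beta_{Ak}}
                     {\sum_l (\bar x_{Al} - \bar x_{Bl})\beta_{Al}},
\qquad
c_k = C \cdot \frac{\bar x_{Bk}(\beta_{Ak} - \beta_{Bk})}
                   {\sum_l \bar x_{Bl}(\beta_{Al} - \beta_{Bl})}.$$

The intercept has identical means in both groups, so it cannot carry an
endowment difference and is excluded from the $E$ share; it does enter
the $C$ share, where it absorbs the baseline difference between groups.
We chose the means-based shares (rather than averaging per-observation
weights) because they make the detailed rows reproducible from the
reported coefficient and mean vectors alone and admit closed-form tests;
the two weightings agree to first order and are close in practice on the
synthetic designs shipped with the package.

An exact linear analogue is kept internally: refitting both groups by
weighted least squares (identity link) collapses $E$ and $C$ to the
classic closed forms $(\bar x_A - \bar x_B)^\top \beta_A$ and
$\bar x_B^\top(\beta_A - \beta_B)$, which the test suite checks to
$10^{-10}$. It is an oracle for testing, not an analysis mode.

### The reference-category problem

Detailed contributions of categorical dummies depend on which level was
omitted during fitting — an identification artifact, not substance. With
`normalize = TRUE` (default) each categorical block is re-expressed in
deviation coding: every level (including the fitting reference) gets an
effect, the block's effects sum to zero, and the shift is absorbed into
the intercept. The linear predictor, and therefore $D$, $E$, $C$, is
unchanged; the detailed rows become invariant to the original choice of
reference (checked to $10^{-8}$ by refitting under every reference).
This is why a published detailed table can show a contribution for
*every* level of every covariate.

### Uncertainty

Standard errors come from a stratified PSU bootstrap: within each design
stratum the PSUs are resampled with replacement, both group models are
refitted, and the decomposition is recomputed (default $B = 200$; a seed
is required, and replicates that fail to converge are dropped and
counted, with more than 20% failures treated as an error). P-values use
a normal approximation on the bootstrap bias-corrected statistic
$2\hat\theta - \bar\theta^*$: the non-linear components carry a small
curvature bias that recurs in every replicate, and subtracting the
replicate mean removes it from the test statistic without touching the
reported point estimates (which must keep $E + C = D$ exactly). We use
the bootstrap rather than a delta method because it respects the
two-stage design without deriving design-consistent analytic variances
for a non-linear functional of two fits.

## The surrounding survey machinery

* **Prevalence** (`svy_prevalence()`): Hajek ratio estimates with Taylor-
  linearized SEs from PSU totals centered within strata. Confidence
  intervals are Wald intervals on the logit scale, mapped back so they
  cannot leave $[0,1]$; the interval is symmetric on the logit scale,
  which is also how the forest plots are drawn. Strata contributing a
  single PSU fall back to grand-mean centering and are flagged — the
  analogue of Stata's `singleunit(centered)`.
* **Pooling** (`pool_prevalence()`): country estimates are combined by
  DerSimonian–Laird random-effects meta-analysis on the proportion scale
  (via `metafor`), the estimator that matches a forest-plot presentation
  of heterogeneous national prevalences; a crude all-country weighted
  prevalence is emitted alongside by the pipeline because the two answer
  different questions and published reports rarely say which was used.
  Zero-SE inputs enter with a configurable minimum variance
  (`min_var = 1e-6`) instead of receiving infinite weight.
* **Bivariable tests** (`svy_chisq()`): Rao–Scott second-order
  (Satterthwaite) corrected chi-square. The generalized-design-effect
  eigenvalues are estimated from the linearized design covariance of the
  independence contrasts; the SRS covariance is evaluated with the same
  $n/(n-1)$ small-sample factor, so under equal weights, singleton PSUs
  and one stratum the test reduces *exactly* to classical Pearson.
* **Collinearity** (`svy_vif()`): classical unweighted VIFs
  $1/(1 - R_j^2)$ on the dummy design, with the mean/min/max summary
  conventionally quoted.
* **Group logits** (`svy_logit()`): pseudo-maximum-likelihood via
  weighted IRLS with Newton polishing and step-halving, converged when
  the score norm falls below $10^{-8}$ (at most 100 iterations);
  covariance is the stratified cluster-robust sandwich. Separation
  (any $|\beta| > 15$) is a hard error naming the term, with
  `firth = TRUE` available for small fixtures; p-values use the normal
  reference, matching large-sample survey practice.

## The synthetic-data generator

`scenario_config()` defines, and `simulate_survey()` draws from, a
multi-country two-stage design: clusters are assigned wholly to the
rural or urban stratum (strata are country-by-residence), covariate
categories follow residence-specific distributions, outcomes are
Bernoulli with group-specific logit coefficients, and Gamma sampling
weights with a configured coefficient of variation are normalized to
mean 1 within country. Two optional features matter for testing:

* a Normal cluster-level intercept (`sigma_cluster`, default 0.3 on the
  log-odds scale) induces intra-cluster correlation, so design-adjusted
  tests genuinely differ from naive ones; the enumeration oracle
  integrates it out by 25-node Gauss–Hermite quadrature;
* an `informative_weights` switch ties the weight to a covariate to make
  weighted and unweighted estimators diverge.

`default_scenario()` freezes the package's reference conditions: 4
countries, 36% urban clusters, and the five covariates that dominate
caesarean-delivery disparities in sub-Saharan African surveys — wealth
(5 levels), antenatal care (3), parity (4), education (4), insurance
(2) — with urban compositions shifted toward high wealth and antenatal
care. Rural coefficients are steeper than urban ones (as the published
group-specific odds-ratio panels show), and intercepts were set with the
enumeration oracle so the true prevalences sit at 10.3% urban and 3.8%
rural, i.e. a total gap of 0.066 splitting roughly 81% characteristics /
19% coefficients — the magnitude reported for the region. The reference
problem size used throughout the acceptance checks is 400 clusters per
country of 25 women (40,000 observations), at which the fitted $E$ lands
within 0.01 of the oracle value.

`true_decomposition()` computes population truth by exact enumeration
over the finite covariate space (all covariates are categorical by
design; continuous covariates are rejected), applying the same
decomposition formulas to the *true* coefficient vectors. Against it the
whole estimation pipeline can be validated without any real microdata.

### What the generator does not emulate

Real DHS data bring non-response and post-stratification corrections,
informative weights, within-cluster covariate correlation beyond the
residence split, and measurement error in self-reported covariates —
none of which are simulated. Passing the synthetic recovery tests
therefore shows the estimators are correct *for the stated design*, not
that any given real-world analysis is free of those further threats.

One subtlety the generator deliberately exposes: with a cluster random
intercept, the marginal success probability is a logit-normal mixture,
so the fitted (population-averaged) logit is mildly misspecified. Groups
with different covariate compositions then have slightly different
pseudo-true coefficient vectors even when the *conditional* coefficients
are shared — a non-collapsibility effect, so the population coefficients
component is not exactly zero under shared conditional betas unless
`sigma_cluster = 0`. The bootstrap calibration checks therefore use an
exactly specified null (single saturated covariate, no cluster effect);
interpretation of $C$ on real data inherits the same caveat.

## Numerical choices and degenerate inputs

* Estimation cells with $p$ exactly 0 or 1 report a degenerate interval
  at $p$ rather than an undefined logit interval.
* A vanishing endowment weight denominator
  ($|\sum_l (\bar x_{Al}-\bar x_{Bl})\beta_{Al}| < 10^{-12}$ with
  $E$ materially nonzero) makes the detailed $E$ shares unidentified;
  this is an error instructing the user to rely on bootstrap totals.
* Rank-deficient designs error out listing the aliased columns, both in
  the logit and in the VIF screen; constant covariates are a
  "degenerate table" error in the chi-square.
* Swapping comparison and reference groups negates $D$ and maps $(E,C)$
  to the opposite weighting convention; the package fixes urban
  coefficients as the endowment weights by default (matching the sign
  pattern of published tables) and exposes the swap through the
  `comparison`/`reference` arguments.
* Weight scale is irrelevant everywhere by construction (all estimators
  are ratio-type); tests assert exact invariance under rescaling.

## Problem sizes used in the checks

The shipped checks run the full chain at 400 clusters/country × 25 women
(40,000 rows) for oracle recovery, 200 null datasets for the
conservativeness comparison with naive Pearson, 1,000 null datasets for
the size of the design-adjusted chi-square, and 500 scenario replicates
× 100 bootstrap draws for the calibration of the coefficients-component
p-value — sizes at which the asymptotic approximations these estimators
rely on are expected to hold for the cluster counts involved.

## A worked run

```{r example, eval = FALSE}
sc <- default_scenario(seed = 1, clusters_per_country = 400L)
data <- simulate_survey(sc)

svy_prevalence(data, by = "group")
dec <- svy_decompose(data, c("wealth", "anc", "parity", "education",
                             "insurance"), boot = 200, seed = 1)
glance(dec)
tidy(dec, level = "variable")
autoplot(dec)

true_decomposition(sc)   # exact population benchmark
```

## Known limitations

* Detailed shares are first-moment approximations; strongly non-linear
  regions (prevalences near 0 or 1) would widen the gap to
  per-observation weighting.
* The bootstrap treats PSUs as the only resampling stage
  (with-replacement draws of $n_h$ PSUs per stratum), which slightly
  understates variance for small numbers of clusters per stratum.
* Jackknife/replicate-weight designs, non-response simulation and
  per-country decomposition are out of scope (the pipeline decomposes
  the pooled two-group contrast; a per-country loop is a thin wrapper
  the user can write over `svy_decompose()`).
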