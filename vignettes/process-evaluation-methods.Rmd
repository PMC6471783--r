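---
title: "Methods: implementation scoring and effect estimation in stepped-wedge process evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implementation scoring and effect estimation in stepped-wedge process evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swpeval)
```

## Setting and data model

swpeval targets the quantitative half of a hybrid
effectiveness-implementation evaluation of a stepped-wedge cluster trial.
The unit of analysis is the *cluster-period cell*: cluster $i$ observed in
calendar period $t$ contributes $n_{it}$ deliveries of which $y_{it}$
experience the (rare) composite outcome, under treatment indicator
$x_{it} \in \{0,1\}$ that, by design, is non-decreasing in $t$ within a
cluster. Around this sit three kinds of per-cluster process data: pre/post
count pairs (coverage of blood-pressure measurement, referral rates),
quantitative implementation measures tagged by domain (fidelity, reach,
adoption) and direction of benefit, and site-level context descriptors.

## The rank-based implementation-strength composite

For each measure, clusters are ranked best-to-worst according to the
measure's declared direction (mid-rank averaging for ties; missing values
are excluded and do not shift the others' ranks). Ranks over $n$ ranked
clusters are rescaled linearly,

$$s = \frac{n - r}{\,n - 1\,},$$

so the best cluster scores 1 and the worst 0. Rescaled scores are averaged
(unweighted) within each domain, and the *available* domain scores are
averaged into the composite. Two consequences matter for interpretation:

* the composite uses only orderings, so any strictly monotone
  transformation of a raw measure leaves it unchanged — this is what makes
  heterogeneous measures (percentages, day counts, ratios) commensurable;
* it is a *relative* score: it positions clusters against each other
  within this trial, not against an external standard.

The linear rescale is the minimal map of ranks onto a fixed $[0,1]$ range;
we deliberately avoid any weighting of domains or latent-variable
alternative, which would import modelling assumptions the design does not
support at $n = 10$ clusters. Missing domains (adoption is typically
unobservable for the latest-crossing sites, whose six-month follow-up
exceeds the trial horizon) are handled by averaging the domains a cluster
has, with `n_domains_used` recorded, so every cluster still receives a
composite. Rank correlations between measures use Spearman's coefficient
— the Pearson correlation of the tie-averaged ranks.

## Pre/post process effects

Unadjusted odds ratios use the Woolf standard error on the log scale.
Zero cells — a real occurrence, since post-intervention coverage of 100%
is observed — are handled by the Haldane–Anscombe correction (0.5 added to
all four cells), applied *only* when a zero is present, or surfaced as an
explicit error when the correction is disabled. Published per-site
"unadjusted comparisons" of coverage are in fact ratios of the post and
pre percentages, so the package provides `proportion_ratio()` alongside
`odds_ratio()` and labels each output by what it is (`kind`), leaving the
choice of measure to the analyst. Computation keeps full precision;
`round_half_up()` exists purely for the display layer because published
tables round half away from zero while R rounds half to even.

## Site-level effect estimation

The estimand is a population-averaged (marginal) treatment odds ratio.
swpeval fits the binomial logistic model by iteratively reweighted least
squares under an *independence working correlation*, and obtains
across-cluster inference from the cluster-robust sandwich covariance

$$\widehat V = \frac{G}{G-1}\, H^{-1}\Big(\sum_g u_g u_g'\Big) H^{-1},
\qquad u_g = \sum_{i \in g} x_i\,(y_i - n_i \hat p_i),$$

with $H$ the observed information and $G$ the number of clusters. This is
the standard marginal-model pairing — the same point-estimate family as an
exchangeable-correlation GEE, with variance valid under arbitrary
within-cluster correlation — chosen over a full GEE because the working
correlation adds no identification at ten clusters while adding opaque
software-specific defaults. It is an approximation to exchangeable GEE and
is documented as such.

Two formulas are exposed. The per-site model is intercept + linear period
trend + treatment; the all-sites model uses fixed centre effects
(categorical) and, by default, separate linear trends per centre
(`per_centre_trends = FALSE` gives a single shared trend — both are
exposed because published descriptions of "separate fixed linear trends"
are ambiguous about centre-by-treatment structure, and per-site fits
sidestep the question entirely).

Numerical choices: the period covariate is centred at its mean (pure
reparameterisation — the treatment coefficient is invariant, the intercept
absorbs the shift — but it conditions the cross-product matrix); the score
convergence tolerance is `1e-8` (max absolute score component) with
step-halving on any likelihood decrease and a hard cap of 100 iterations;
fitted probabilities are clamped to `[1e-12, 1 - 1e-12]`; separation is
flagged (`converged = FALSE`, with a warning) rather than silently
returning drifting coefficients; zero-event and even zero-delivery cells
are retained — they contribute through the likelihood (with zero weight
when empty), and ad-hoc cell dropping would bias the trend estimate.

## Meta-analysis and meta-regression

Site log effects $y_i$ with standard errors $se_i$ are pooled by
DerSimonian–Laird: $Q$ on fixed-effect weights $w_i = 1/se_i^2$,

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

then inverse-variance pooling with weights $1/(se_i^2 + \hat\tau^2)$.
Meta-regression uses the same method-of-moments logic on the regression
residual statistic $Q_E$, with $\hat\tau^2_{res} = \max(0, (Q_E - (k-p)) /
\operatorname{tr}(P))$, followed by weighted least squares; the slope is
reported per unit of the $[0,1]$ composite, also exponentiated. The
method-of-moments estimator was chosen because it is deterministic and
closed-form — procedure fidelity is the contract here, since per-site
event data rich enough to replicate any published meta-regression
numerically are not available. All pooling happens on the log scale;
exponentiation is display-only. The Knapp–Hartung adjustment (variance
rescaling plus $t$ quantiles) is off by default to keep the default Wald
behaviour transparent, and available by flag for small-$k$ robustness.

Both estimators agree with an independent implementation (metafor, DL
method) to machine precision on fixed fixtures in the test suite; that
package serves only as a cross-check, never as the computation path.

## The synthetic-trial generator

`generate_design()` allocates clusters to steps by uniform random
permutation of a balanced step vector (remainder clusters round-robin over
the earliest steps) and runs the trial for
$(\text{steps}+1)\times\text{periods-per-step}$ periods — ten clusters in
nine two-period steps give the 20-period layout the package is designed
around. `simulate_trial()` draws deliveries as Poisson around per-cluster
mean volumes (log-normal between clusters) and events as Binomial with

$$\operatorname{logit} p_{it} = \operatorname{logit}\pi_0 + u_i +
\gamma_i t + \beta\, x_{it}.$$

Generator defaults describe the emulated trial: baseline risk
$\pi_0 = 7\times10^{-4}$ (a few events per 10,000 deliveries), ~2600
deliveries per cluster-month with a between-cluster CV of 0.5 (central
plus peripheral facility volumes of this scale and spread), centre-effect
SD 0.3 and trend SD 0.005 on the log-odds scale (modest unexplained
between-site variation and secular drift). One integer seed drives
everything through a documented splitting rule (sub-seeds drawn from the
master-seeded stream, one per stage), so any stage is reproducible in
isolation.

`simulate_implementation()` generates the five emulated process measures
on the logit scale as `base + coupling × benefit + noise`, with benefit
$= -\beta_i$; positive coupling therefore means better-implemented
clusters have stronger protective effects, giving recovery experiments a
known meta-regression slope sign. Adoption is right-censored for the two
latest steps by default, mirroring the stepped-wedge horizon problem.

What the generator does **not** emulate — and hence what passing recovery
tests do not certify about real data: informative missingness in process
reporting, overdispersion of events beyond binomial within a cell,
referral-network spillover between clusters, calendar shocks (strikes,
natural disasters) that real multi-country trials record, and measurement
error in the denominators. The validation shows the estimators do what
they claim under their own assumptions, not that those assumptions hold in
any particular trial.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate by parameter recovery
at sizes chosen to make Monte-Carlo error small relative to the effects of
interest while the whole suite stays comfortably interactive: treatment
log-OR recovery over 200 replicates of a 10-cluster × 20-period trial at
1000 deliveries per cell (baseline risk 0.01); type-I error of the
treatment Wald test over 500 null replicates at 500 deliveries per cell;
and the full chain — simulate, per-site fits, scoring, meta-regression —
over 500 replicates at 500 deliveries per cell and baseline risk 0.02
(about ten events per cell), checking that the slope on an uncoupled
composite is centred at zero with ~95% CI coverage. Coverage checks use
99% binomial bounds around the nominal level.

## Known limitations

* With $G = 10$ clusters the sandwich variance with normal critical values
  is anticonservative; the type-I-error validation therefore uses the
  model-based Wald test under a correctly specified generator, and the
  robust-variance checks use designs with more clusters. For real
  ten-cluster inference, prefer the Knapp–Hartung flag at the meta layer
  and treat marginal-model robust SEs with caution.
* DL $\hat\tau^2$ is noisy at $k \le 10$ and truncated at zero;
  heterogeneity statistics from ten sites are descriptive, not precise.
* The composite score is ordinal in spirit: a difference of 0.1 has no
  absolute meaning, and comparisons across trials are not meaningful.
* Per-site logistic fits require events in both arms of the site; sites
  crossing over at the very end of a short series can be inestimable and
  are dropped (with a warning) from the meta layer.
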