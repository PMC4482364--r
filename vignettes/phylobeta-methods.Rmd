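---
title: "Methods: phylogenetic beta regression for range decline"
author: "phylobeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic beta regression for range decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylobeta)
```

## The model and its assumptions

`phylobeta` models a proportion-valued trait — proportional geographic
range decline — across a clade while accounting for phylogeny. Each
analysis taxon $i$ contributes a response $y_i \in (0,1)$ with

$$y_i \sim \mathrm{Beta}(\mu_i\gamma,\ (1-\mu_i)\gamma),\qquad
\mathrm{logit}(\mu_i)=\mathbf{x}_i^\top\boldsymbol\theta+u_i,\qquad
\mathbf{u}\sim\mathrm{MVN}(\mathbf 0,\ C_\lambda).$$

The mean–dispersion parameterisation makes $\mu_i$ the expected decline
and $\gamma$ a concentration: small $\gamma$ (the regime typical of
decline data, $\hat\gamma\approx 0.5$) gives a U-shaped distribution with
mass near 0 and 1 — many stable species, some nearly extirpated.

$C$ is the phylogenetic variance–covariance matrix (shared root-to-MRCA
branch length), and $C_\lambda$ multiplies its off-diagonal by Pagel's
$\lambda$. The species effects therefore interpolate between independent
($\lambda=0$) and Brownian-motion ($\lambda=1$) covariance. Assumptions
worth keeping in mind:

* the tree is rooted with branch lengths on a meaningful scale; trees
  need not be ultrametric and no depth rescaling is applied by default.
  Because the MVN species prior has **no free scale parameter** (its
  covariance is exactly $C_\lambda$), the magnitude of the random effects
  on the logit scale is tied to tree depth. The branch-length units of a
  composite literature phylogeny are rarely stated, so this is an
  interpretive, not a correctness, issue; it affects how much variance
  the species effects can absorb relative to $\gamma$.
* a species present in both regions enters twice, as two analysis taxa
  with distinct traits mapped to the same tip.
* the response must be strictly inside $(0,1)$ for the beta likelihood
  (see the compression rule below).

## Priors and their parameterisation

* Coefficients: $N(0, 1000^2)$ — effectively flat on the logit scale.
* $\lambda \sim U(0, 1.2)$. For $\lambda \le 1$, $C_\lambda$ is always
  positive semidefinite; for $\lambda \in (1, 1.2]$ it can lose positive
  definiteness, in which case the sampler assigns the proposal a log
  posterior of $-\infty$ rather than silently truncating the prior. With
  duplicated taxa the duplicate block $\begin{pmatrix}d&\lambda d\\
  \lambda d&d\end{pmatrix}$ is singular at $\lambda = 1$ and indefinite
  above it, so duplication effectively confines $\lambda$ below 1.
* Dispersion: the gamma prior is stated as "shape and scale = 0.001",
  which read literally (shape–scale) implies a prior mean of $10^{-6}$.
  The model this package follows was fitted in software whose gamma
  distribution is shape–rate, under which the same words give a diffuse
  prior with mean 1. We default to shape = 0.001, **rate** = 0.001 and
  expose `gamma_prior_parameterization = "rate" | "scale"` in
  `model_spec()` so either reading is available.

## Handling zeros and ones in the response

Observed range declines contain many exact zeros (stable species) and
can contain ones. The beta density has support $(0,1)$, so
`prepare_predictors()` applies the Smithson–Verkuilen compression
$y' = (y(n-1)+0.5)/n$ by default ($n$ = number of analysis taxa),
order-preserving and invertible. A fixed $\varepsilon$-clamp and a pass
through (`squeeze = "none"`) are available.

One consequence discovered during development and worth documenting: the
compression maps all exact zeros to the *same* interior value $0.5/n$.
A pile of identical response values is fitted best by a very concentrated
beta — so on data whose zeros are artificial (e.g. synthetic beta draws
that underflowed to machine zero), the compressed response can drive the
$\gamma$ posterior to very large values and the model toward
interpolation by the species effects. Synthetic responses drawn from the
model are already strictly interior, so the parameter-recovery machinery
fits them with `squeeze = "none"`; the compression is a measurement
model for genuinely censored-at-zero field data, not a cosmetic step.

## Duplicated taxa

Two populations mapped to one tip are treated as sister lineages of zero
divergence: each keeps the tip's root-to-tip variance $d$, and their
mutual covariance is $d$ before the transform, hence $\lambda d$ after —
the same rule every other off-diagonal follows. Residual between-region
differences are absorbed by the beta dispersion (and by the region
fixed effects).

## The sampler

The posterior is sampled by adaptive Metropolis-within-Gibbs, in a
compiled core:

* each coefficient $\theta_j$: scalar Gaussian random walk;
* each species effect $u_i$: scalar random walk, with the MVN prior term
  updated incrementally through the precision matrix of $C_\lambda$;
* a *translation move* proposing $(\theta_0+\delta,\ \mathbf u-\delta)$,
  which leaves the linear predictor unchanged and therefore traverses
  the intercept/mean-of-$u$ ridge that single-site updates cross slowly
  (the intercept is consistently the slowest-mixing parameter, and its
  effective sample size the smallest, without this move);
* $\gamma$: random walk on $\log\gamma$ with Jacobian;
* $\lambda$: random walk with rejection outside $[0, 1.2]$ and at
  proposals whose $C_\lambda$ fails its Cholesky factorisation.

Each proposal scale adapts toward a 0.44 acceptance rate in batches of
50 iterations **during the discarded adaptation phase only**, so the kept
chains are draws from a fixed Markov kernel. Defaults are 4 chains of
500 adaptation + 5000 kept iterations — desk-scale settings chosen so a
full two-form fit of ~70 taxa takes a few seconds; the study-scale
1000 + 50000 is a configuration choice away. All randomness flows from
one master seed through deterministic per-chain substreams: the same
seed reproduces chains bit for bit.

A generic R-level `run_chains(logpost, init, ...)` implements the same
scheme for arbitrary log-densities; it is the calibration surface (exact
normal targets, conjugate posteriors) and a plug-in point for alternative
samplers behind the same contract. Gradient-based samplers would mix
faster per iteration but none of the package's claims depend on the
sampler family; correctness is checked against analytic targets instead.

## Diagnostics and summaries

* **Split-chain Gelman–Rubin**: each chain is halved and
  $\hat R=\sqrt{((n-1)/n\,W + B/n)/W}$ computed over the halves, which
  detects within-chain drift that the unsplit statistic misses. All-equal
  halves return `NA` with a degeneracy flag.
* **ESS**: $n/(1+2\sum_k\rho_k)$ with biased ($n$-denominator)
  autocorrelations summed by the initial-positive-sequence rule
  (truncate just before the first $k$ with $\rho_k+\rho_{k+1}\le 0$),
  capped at $n$; a constant chain reports 1 with a flag. Inference
  follows the combined-chain protocol: after diagnostics, chains are
  concatenated and ESS/MCSE computed on the single combined sequence.
* **HPD interval**: shortest contiguous window of the sorted draws
  containing $\lceil 0.95\,n\rceil$ draws; width ties — which occur
  exactly on gridded draws — break toward the lower start, with a
  $10^{-9}\times\mathrm{range}$ tolerance so floating-point noise cannot
  flip the tie.
* **MCSE** = sd/$\sqrt{\mathrm{ESS}}$. Summary tables report both the
  posterior sd and the MCSE; the "SE" column of the source tables is far
  too small to be a posterior sd and is reproduced by the MCSE.
* **Notable effects**: coefficient rows are flagged when the 95% HPD
  interval excludes zero. $\gamma$ and $\lambda$ have positive support,
  so an exclude-zero test is vacuous; they are reported (and starred) as
  model parameters instead.

## The synthetic-data generator

`synthetic_config()` fixes the simulated study conditions:

* **Tree**: Yule process, 60 species, birth rate 1 (origin-to-tip depth
  $\mathbb E = 1 + \sum_{k=2}^{60} 1/k \approx 4.7$, with the stem kept
  as a root edge). The real clade has 61 mainland species.
* **Duplication**: each species straddles the regional boundary with
  probability $8/61$, matching the eight straddling species of the
  motivating fauna; straddlers duplicate the tip rather than adding
  zero-length sister tips, so synthetic and real pipelines are
  identical.
* **Predictors**: log-normal range size (median $e^{12}\approx 1.6\times
  10^5$ km²), rainfall (median 600 mm), female mass (median 60 g, the
  small-bodied rodent range), litter size (median 3.5); habitat-openness
  ranks weighted toward open habitats (0.30, 0.25, 0.20, 0.15, 0.10) as
  in arid-zone faunas. These are realistic scales for the system; the
  model standardises them away, so only their ordering structure
  matters.
* **Truth**: intercept −1.66, NS 1.22, log Range −0.45, habitat openness
  −0.61 (others 0), $\gamma=0.5$, $\lambda=0.8$ — echoing the magnitudes
  of the fitted main-effects model so that tests exercise a realistic
  signal-to-noise regime.
* **Genus labels** are the maximal clades below half the tree height —
  arbitrary but deterministic, used only by the genus-incidence
  tabulations.

What the generator deliberately does **not** emulate: predictors are not
themselves evolved along the tree (only the species effects are
phylogenetically structured, exactly as in the fitted model); ranges are
not spatial objects, so region assignment is a coin flip rather than a
centroid computation; and there is no measurement error in the traits.
Passing recovery tests therefore demonstrate that the *inference
machinery* is correct and calibrated under the model's own assumptions —
they cannot validate those assumptions against real field data.

With $\gamma=0.5$ and strongly negative linear predictors, beta shape
parameters reach $10^{-2}$–$10^{-3}$ and a non-negligible fraction of
draws underflow to machine zero in double precision; responses are
clamped to $[2.2\times10^{-308},\ 1-10^{-12}]$, which is immaterial to
the likelihood (the log-density is continuous there) but keeps the
support constraint intact.

## Numerical choices

* Positive-semidefiniteness tolerance: smallest eigenvalue
  $\ge -10^{-8}\,\mathrm{tr}(C)$; MVN densities are computed by Cholesky
  and a factorisation failure is treated as $-\infty$ (outside the
  support), never as an exception mid-chain.
* `beta_logpdf()` returns $-\infty$ (not an error) for responses or
  parameters outside the support, so samplers can reject freely.
* Region boundary: the Tropic of Capricorn at $-23.43665^\circ$; a
  centroid exactly on the line is "south" ("north of the Tropic" read
  strictly).
* Decline categories partition $[0,1]$ as $\{0\}$, $(0,0.25]$,
  $(0.25,0.5]$, $(0.5,1]$ — the contiguous half-open partition closest
  to the printed labels "< 25%", "26–50%", "> 50%", whose gap between
  25% and 26% must be assigned somewhere.
* Missing data: listwise deletion with the dropped taxa reported, since
  the motivating analyses describe no imputation.
* Genus incidence counts *species*, not populations: a straddler
  declining in either region counts once, as declining.

## Problem sizes used by the tests

The shipped suite runs at desk scale, chosen so the whole suite completes
in about a minute and a half: parameter recovery uses 20 replicates of
60-species trees fitted with 4 × (500 + 5000) iterations; sampler
calibration uses 20000 kept draws on an analytic bivariate normal;
prior recovery (likelihood disabled) uses 4 × (3000 + 6000) draws with a
proposal scale initialised near the prior sd; diagnostic benchmarks use
AR(1) chains of 50000 draws. The acceptance script repeats these
computations from scratch at the same sizes under a user-supplied seed.

## Known limitations

* Metropolis-within-Gibbs mixes more slowly than gradient-based samplers
  on strongly correlated posteriors; the intercept and $\lambda$ have
  the smallest effective sample sizes. The chain-set contract is sampler
  agnostic, so a faster kernel can be substituted.
* The species-effect prior has no free variance multiplier (by design,
  matching the model reproduced here); on trees whose depth is small
  relative to the logit-scale spread of the data the random effects will
  be under-dispersed, and vice versa. An optional scale is a natural
  extension but defaults to off.
* Model comparison (information criteria, cross-validation) and
  zero-one-inflated beta variants are out of scope.
* Random-forest / conditional-inference-tree analyses of decline
  occurrence, and the GIS derivation of range centroids and rainfall,
  are upstream of this package: it consumes their outputs as columns of
  the trait table.
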