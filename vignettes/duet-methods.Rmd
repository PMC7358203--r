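---
title: "Joint Bayesian modelling of differential expression and splicing with duet"
author: "duet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian modelling of differential expression and splicing with duet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duet)
```

## Motivation

RNA-seq experiments quantified at the transcript level (Salmon, RSEM,
kallisto, StringTie, long-read pipelines) carry two distinct biological
signals: a change in a gene's total transcriptional output between
conditions (differential gene expression, DGE), and a change in the
*relative usage* of the gene's isoforms (differential alternative splicing
and transcription, DAST).  Most tools interrogate one signal and treat the
other as a nuisance.  `duet` models both in a single hierarchical Bayesian
model, so that every gene receives a posterior probability of expression
change and a posterior probability of splicing change, and can be placed in
one of four groups: expression-regulated (DGE), splicing-regulated (DAST),
both (DAST/DGE), or static.

## The model

All observations are log2 counts-per-million, `log2(cpm + 0.5)`, where cpm
uses each sample's total isoform count as the library size.  For one gene
with $T$ isoforms, $n_1$ control and $n_2$ case samples:

* **Expression block.**  The control mean log2-cpm is $\beta_0$ and the
  case-minus-control shift is $\beta$ (log2 units):
  $$\beta \sim \mathcal N(0, 5), \qquad
    \beta_0 \sim \mathcal N(\mu_1, 5),$$
  with $\mu_1$ the observed mean control log2-cpm of the gene and 5 a
  variance on the log2 scale (a weakly informative choice: most shifts are
  within a few log2 units).  Gene-level observations $y_s$ (the log2-cpm of
  the summed isoform counts) are Normal around $\beta_0$
  ($\beta_0 + \beta$ in cases) with per-observation variances
  $\hat\sigma^2_s$ taken from the gene-level mean-variance trend below.

* **Composition block.**  Control isoform usage is a point
  $p = (p_1, \dots, p_T)$ on the simplex with a flat Dirichlet(1) prior.
  Case usage is linked to control usage through the Aitchison perturbation
  $$p'_i = \frac{p_i\,\alpha_i}{\sum_{j} p_j\,\alpha_j},$$
  where $\alpha$, also Dirichlet(1), is the perturbation vector.  The
  uniform vector $(1/T,\dots,1/T)$ is the identity element of the simplex
  group, so "no differential splicing" is exactly "$\alpha$ uniform".
  Each isoform observation, *centred on the gene's observed log2-cpm in
  that sample*, is Normal around $\log_2 p_i$ (controls) or
  $\log_2 p'_i$ (cases), with variances from the isoform-level trend.

Centring the isoform observations on the observed per-sample gene level is
a deliberate design choice.  Isoform levels are fractions of the gene
level, and the gene-level observation is (deterministically) the sum of
the isoform observations; anchoring both blocks on $\beta_0$ would count
the same reads twice and shrink the posterior of $\beta$ by roughly
$\sqrt 2$.  With the centred parameterization the likelihood factorizes
cleanly into a total-abundance part (informing $\beta_0,\beta$) and a
composition part (informing $p,\alpha$), and null genes attain their
nominal posterior coverage.  Genes with a single retained isoform have no
composition block and are analysed for expression only.

### Mean-variance trend

A common mean-variance trend supplies the observation variances: for every
row of the (gene-level or isoform-level) log2-cpm matrix a two-group-means
linear model is fitted, giving a residual standard deviation $s$ and a row
mean $m$; a LOWESS curve (span 0.5, 3 robustifying iterations, both
configurable) through $(m, \sqrt s)$ is the trend, and an observation's
variance is the fourth power of the trend value at the row's
condition-specific fitted mean.  Gene-level and isoform-level trends are
fitted independently, and evaluation outside the fitted support is clamped
to the boundary.  Because $s$ is computed from few residual degrees of
freedom, $(\widehat{\sqrt s})^4$ carries the usual small-sample
chi-distribution bias (of order 10--15% at $n = 10$); we keep the
estimator in its plain form, which makes posterior intervals very slightly
anticonservative at small $n$.

### Posterior summaries

With posterior draws in hand (default: one chain, 2000 warmup of 10000
total iterations):

* `probDE`: the fraction of $\beta$ draws on the same side of zero as the
  posterior mean (draws at exactly zero count to neither side).
* `probDSGene`: for each isoform, the larger of the posterior mass of
  $\alpha_i$ above and below $1/T$; the gene-level call is the maximum over
  isoforms.
* `probDSIsoform`: the isoform-level variant replaces the null point $1/T$
  by the draw-wise dot product $\alpha \cdot p$, which equals $1/T$ when
  $\alpha$ is uniform but not in general.
* Fold changes: the expression log2 fold change is the posterior mean of
  $\beta$; the splicing fold change of isoform $i$ is the Aitchison
  perturbation of the (renormalized) posterior mean of $p$ by the
  posterior mean of $\alpha$, divided by the mean of $p$.
* Classification at thresholds 0.99 (gene level) and 0.999 (isoform
  level), both configurable: DGE / DAST / DAST-DGE / static according to
  which probabilities exceed their thresholds.  For multi-comparison
  designs, `aggregateCohorts` counts a comparison as DE (DS) when called
  in at least 3 sub-cohorts and labels a gene splicing-regulated when DS
  calls are at least twice as frequent as DE calls, and conversely.

## Sampling

Given $(p, \alpha)$ the expression block is linear-Gaussian, so
$(\beta_0, \beta)$ has a bivariate normal posterior that the sampler draws
from exactly; in the factorized model this conditional does not depend on
the composition block at all, so these draws are iid.  The simplex vectors
are updated by random-walk Metropolis on additive-log-ratio coordinates
with three moves: a $p$ move, an $\alpha$ move, and a joint "ridge" move
that adds the same perturbation to $p$'s coordinates and subtracts it
from $\alpha$'s.  The ridge move matters because the case fractions
depend on $(p, \alpha)$ only through the product $p_i\alpha_i$, leaving
an anti-correlated direction that blockwise moves traverse slowly; moving
along it leaves the case fractions invariant.  Each stored iteration runs
several such sweeps (three by default, more for genes with many isoforms,
since random-walk mixing slows with dimension); global step sizes adapt
towards 30% acceptance during warmup (blocks of 50 proposals) and
per-coordinate proposal scales are learned from the warmup chain's
coordinate variances; both are frozen at the end of warmup so the
post-warmup kernel is a fixed Markov kernel.  All randomness flows from R's RNG, so a run is reproducible
from `set.seed`.  Initial values follow the observed data: $\beta = 0$,
$\beta_0 = \mu_1$, $p_i = 2^{\bar{tr}_i}/\sum_j 2^{\bar{tr}_j}$ from the
mean control isoform log2-cpm, $\alpha_i = 1/T$ (with exact conditional
draws for $(\beta_0,\beta)$, their initial values do not enter the chain).

Convergence is monitored with the Geweke diagnostic
(`gewekeDiagnostic`): the means of the first 10% and last 50% of each
parameter's chain are compared with spectral-density standard errors, and
the fraction of Benjamini-Hochberg-significant p-values at 0.05 is
reported.  On converged runs of a full simulated dataset this fraction is
0.  An independent implementation of the same model in JAGS is used in the
test suite to cross-check the posterior; it is a validation device, not a
backend.

## The simulator

`simulateDataset` generates isoform-level counts with known ground truth:

* Gene expected proportions are log-normal (`sdlog = 1.5`) normalized to
  sum 1 — a heavy-tailed abundance distribution typical of bulk RNA-seq.
* Each gene receives 2--10 isoforms with probabilities
  0.4, 0.2, 0.1, 0.05 (x6), and its proportion is split evenly among them.
* DE genes (10% by default) have the whole gene's proportion doubled in
  one randomly chosen condition (true |log2 fold change| of 1).
* DS genes (10% by default, disjoint from the DE set by default) have one
  random isoform's proportion doubled in cases and a *different* isoform's
  doubled in controls, which leaves the gene's expected total unchanged
  and gives the two boosted isoforms within-gene fraction fold changes of
  exactly 2 and 1/2 for every $T$.
* Counts are negative-binomial with mean `library_size x proportion` and a
  genewise dispersion `0.1 + 1/Gamma(shape 10, scale 25)` (mean about
  0.104, a biological CV near 0.32; the scale parameterization is chosen
  so the baseline 0.1 dominates — a rate of 25 would give dispersions near
  3, which no bulk RNA-seq experiment shows).  Library sizes are either
  all equal to 2e6 or drawn uniformly from [2e6/3, 3·2e6].
* Defaults: 1000 genes and 5 samples per group — desk-scale; the study
  design scales to 10^4 genes by configuration.

After effect injection the per-condition proportions are renormalized over
all isoforms for sampling.  The truth table records the
*pre-renormalization* gene totals (for which the DS invariance is exact)
and the within-gene fractions, which the global renormalization cannot
affect.  The simulator draws each isoform independently, so it does not
reproduce positional or mapping biases, isoform-assignment uncertainty
from shared exons, or correlated library composition effects of real
quantifiers — passing benchmarks here shows correctness of the method
under its own assumptions, not performance on any particular real dataset.

## Evaluation utilities

For benchmarking on simulated data the package provides: `ostpCurve`, an
oracle baseline that computes per-isoform two-sample Welch t statistics on
isoform proportions (each isoform's count divided by the sum of the
gene's *other* isoforms) and, for every achievable false-positive count,
picks the |t| cutoff maximizing detected true positives (true positives
being truly differentially spliced isoforms with fold change at least 2) —
an upper bound for t-statistic-based splicing detection that requires
ground truth; `prCurve`, a precision-recall sweep over a [0, 1] statistic
grid in steps of 1e-4 with trapezoidal area over the recall envelope; and
`meanPRCurve`, which LOWESS-smooths precision over recall per dataset,
imputes missing precision values from the nearest lower recall, and
averages pointwise.

On five simulated datasets (1000 genes, seeds 1--5, defaults, 2000/10000
MCMC) the acceptance suite verifies the qualitative benchmark: the
posterior splicing probabilities dominate OSTP, and the posterior DE
probabilities match or beat per-gene t-tests on gene-level log2-cpm, in
mean area under the precision-recall curve.  Shorter chains are supported
but discouraged for ranking tasks: with $D$ draws the probabilities are
quantized at $1/D$, and once many genes saturate at probability 1 the
ranking inside that tie is lost.

## Numerical choices and edge cases

* Compositions are validated to sum to 1 (tolerance 1e-6 on input),
  entries at or below zero are floored at 1e-12 and renormalized; the
  perturbation is undefined at exact zeros.
* Draws numerically at a splicing null point (within 1e-10) count to
  neither side, mirroring the sign convention for $\beta$ draws at zero.
* Isoforms must have a count of at least 1 in every sample (configurable)
  to enter the model; genes losing all isoforms are dropped, genes left
  with one isoform become expression-only.
* A zero library size, an all-zero-variance dataset, or a truth table
  without positives raise immediate errors rather than propagating NaNs.
* OSTP skips isoforms whose proportion is undefined (zero complement) or
  whose t statistic is degenerate, with a warning.
* `aggregateCohorts` breaks the dominance tie "DS calls exactly twice DE
  calls" towards DAST ("at least twice"), and symmetrically for DGE.

## Problem sizes used in the test suite

Unit tests run on 10--300 gene simulations with shortened chains; the
acceptance suite uses five 1000-gene datasets at the default 2000/10000
chain length, 50 DE genes for bias assessment, 20 model-simulated null
genes for calibration, and 10^4 genes for simulator distribution checks.
These sizes were chosen so the full suite completes on a laptop-class
single core in minutes while keeping every Monte-Carlo margin (binomial
3-sigma bands, +-0.02 AUPRC tolerance) comfortably wider than the
sampling noise at that scale.

## Known limitations

* Two-condition designs only; no covariates, no multi-group contrasts.
* The Normal observation model on log2-cpm relies on the mean-variance
  trend; very low counts (below the default filter) are excluded rather
  than modelled.
* Posterior probabilities are reported raw, without frequentist FDR
  calibration; thresholds are the user's choice.
* The trend readback keeps the plain $(\sqrt s)^4$ estimator, slightly
  underestimating variances at very small sample sizes (see above).
* OSTP requires ground truth and is meaningful only on simulated data.
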