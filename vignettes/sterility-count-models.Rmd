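---
title: "Models for chemically induced sterility counts in wheat crossing blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models for chemically induced sterility counts in wheat crossing blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterilecount)
```

## The problem

Hybrid wheat seed production relies on male sterility of the female parent.
When sterility is induced chemically (a chemical hybridizing agent, CHA,
such as sintofen), its efficacy varies by genotype and season, and it is
measured by bagging individual heads under pollen-impermeable bags and
counting the seeds that form by self-pollination. A fully sterilized head
sets zero seeds; a partially sterilized head sets a handful; an untreated
healthy head would set around 30. The resulting data are counts per bagged
head in a randomized complete block design with subsampling: each genotype
occupies one plot (the experimental unit) per block, and several bagged
heads (sampling units) are scored within each plot. Bags lost to wind make
the data unbalanced.

These counts are severely zero-inflated (38–64% zeros in the two seasons
the package's reference configurations emulate), right-skewed, and
overdispersed, which defeats both the classical normal-approximation
analysis of (transformed) counts and plain Poisson models. The package
implements the full ladder of analyses a breeder would compare:

* **threshold (logit/probit) GLMMs** on the binary event "the head set at
  most `t` seeds" (default `t = 7`, i.e. roughly 75% sterility of a
  30-seed head) — a quick screen for genotype differences;
* **count mixed models**: Gaussian (identity), Gaussian on `log(y+1)`,
  `sqrt(y+3/8)` and `y^(2/3)` transformed responses, Poisson, negative
  binomial (NB2), zero-inflated negative binomial (ZINB), and hurdle
  negative binomial (HNB);
* an **empirical-coverage simulation study** quantifying what each model's
  nominal 95% confidence intervals are worth when counts truly arise from a
  zero-inflated process.

## The models

All models share the linear predictor
$\eta_{ijk} = \alpha_i + b_j + (\alpha b)_{ij}$,
with genotype fixed effects $\alpha_i$, i.i.d. normal block effects
$b_j \sim N(0, \sigma_b^2)$ and whole-plot (genotype-by-block) effects
$(\alpha b)_{ij} \sim N(0, \sigma_{ab}^2)$. The whole-plot term is the
experimental-unit error above head-level sampling.

The two mixture families differ only in how zeros arise. With $f$ the NB2
pmf with mean $\lambda$ and dispersion $k$ (variance
$\lambda + \lambda^2/k$):

* **zero-inflated**: $\Pr(Y=0) = \pi + (1-\pi) f(0)$ and
  $\Pr(Y=y) = (1-\pi) f(y)$ for $y \ge 1$ — zeros arise both structurally
  (probability $\pi$, full sterilization) and from the count process
  (random kernel abortion etc.);
* **hurdle**: $\Pr(Y=0) = \pi$ exactly, and positive counts follow the
  zero-truncated NB, $\Pr(Y=y) = (1-\pi) f(y) / (1 - f(0))$ — every zero
  is attributed to the CHA.

$\pi$ is the *inflation probability* (logit scale in the fits, one per
genotype or one overall), and $\lambda$ the genotype's mean seed count of
the seed-forming count component. Random effects enter the count
component's log mean; the inflation predictor carries genotype fixed
effects only, because a single extra random term is already at the edge of
what 4 blocks support.

## Estimation

The marginal likelihood integrates the random effects out. The engine
implements three interchangeable approximations behind one surface
(`marginal_loglik()`):

* **Laplace**: a Newton search for each random-effect level's conditional
  mode (using analytic first and second derivatives of every family's
  conditional log-likelihood) and a second-order expansion;
* **adaptive Gauss–Hermite quadrature (AGQ)**: the same mode and curvature
  recenter and rescale a Gauss–Hermite rule (default 9 nodes);
* **dense non-adaptive Gauss–Hermite**: a brute-force reference used by the
  test suite as an oracle.

With both random terms present the block integral is evaluated by nesting
the per-plot integrals inside each outer quadrature evaluation, which is
exact for the nested (block / whole-plot-within-block) structure. When all
variance components are zero the marginal collapses to the sum of
conditional log-densities, and the test suite asserts this identity
exactly. Following the convention of the mixed-model software family this
ladder originates from, the count families use Laplace ML, the binary
threshold families AGQ, and the (transformed-)Gaussian families REML — the
REML criterion is evaluated in closed form through the dense marginal
covariance, with the genotype effects profiled out.

The optimizer is bounded quasi-Newton (`L-BFGS-B`) on a transformed space
(log variance components, log dispersion, logit inflation), with analytic
scores for models without random terms and numeric gradients otherwise;
mixture fits retry from deterministically jittered starts when the first
attempt fails. Non-convergence is reported, never thrown. Wald covariance
comes from the observed information at the optimum; parameters at the
search bounds (all-zero genotypes, complete separation) are flagged
non-estimable rather than silently returned — with per-genotype inflation
on small data this happens exactly as over-parameterization warnings.

Numerical choices worth knowing: the zero cell of the zero-inflated pmf is
evaluated by log-sum-exp; the hurdle zero cell is returned as $\pi$
bit-exactly; linear predictors are clamped at $\pm 30$ on the log scale;
quadrature modes are warm-started across optimizer iterations (pure
speed-up; results are identical within the $10^{-9}$ Newton tolerance).

### Degrees of freedom and tests

`type3_genotype_test()` is a Wald-type F test of equal genotype effects.
Its default denominator df is the residual rule $n - p$, which tracks the
large-sample chi-square reference; the containment rule $(G-1)(J-1)$ is
available as an option. The Wald statistic for genotype proportions is
already light-tailed at trial-sized designs once proportions are extreme
or block heterogeneity is present with only four blocks, and the
containment rule's much smaller reference df compounds that conservatism.
The residual rule holds its size under a clean null — equal interior
proportions and no block noise — which is how the test suite measures it
(empirical size 0.03 at a nominal 0.05 over 500 replicates). A consequence worth
stating plainly: with four blocks and 20 heads per genotype, a
non-significant genotype test is weak evidence of no genotype differences.

`information_criteria()` uses the small-sample corrected
$AICc = -2\ell + 2p + 2p(p+1)/(n-p-1)$ with $n$ the number of heads (not
experimental units) and $p$ every estimated parameter; both conventions
differ across software, so they are fixed and documented here.
Transformed-scale Gaussian fits are never ranked against count
likelihoods: `compare_count_models()` marks the likelihood types and sorts
within them.

## The synthetic generator

`simulate_crossing_block()` draws data exactly as the models assume:
per-head Bernoulli($\pi_g$) structural zeros, NB2 (or zero-truncated NB2
for the hurdle process) counts with mean
$\exp(\log \lambda_g + b_j + (\alpha b)_{ij})$, and independent
(missing-completely-at-random) bag loss. Two reference configurations,
`trial_config(2015)` and `trial_config(2016)`, emulate the two seasons of
the reference CHA trial:

* **2015**: the 26 genotype-specific hurdle-NB estimates of
  `genotype_reference()` ($\lambda$ from 2.56 to 25.75 seeds,
  $\pi$ from 0.12 to 0.67), hurdle process, bag loss solved so the
  expected record count is 371 (of 520 cells).
* **2016**: genotype-level estimates were not published for that season,
  so all genotypes share one $(\pi, \lambda)$ pair solved at run time so
  the marginal zero proportion is 0.64 and the marginal mean 2.6 seeds
  per head, with bag loss giving 182 expected records.

The NB dispersion defaults to $k = 1$: with the 2015 genotype spread, a
moment match to the season's observed variance (65 at mean 5.7) puts $k$
near 1, and the paper trail behind the reference estimates does not report
one. Random-effect SDs default to zero in the reference configurations so
that the configured $\pi_g, \lambda_g$ are exactly the marginal head-level
parameters; block and whole-plot SDs are free parameters for users who
want design noise.

What the generator does *not* emulate: spatial field structure, weather
covariates, informative bag loss, pollination biology, or genotype-by-year
correlation. Tests passing against this generator demonstrate that the
estimation machinery is correct under the stated model, not that the model
is right for any particular field dataset.

## The coverage study

`run_coverage_study()` repeats, many times: simulate one crossing-block
experiment from a zero-inflated NB process (default: the 2015
genotype-level parameters, an 8-genotype subset spanning the full range of
$\lambda$ and $\pi$, 4 blocks of 5 heads, no design noise), fit each model
of the ladder, form nominal 95% confidence intervals for each genotype's
reported seed-count estimate on the data scale, and record the binary
indicator of whether the interval contains the generating value. Defaults
run the two-batch, 500-experiments-per-batch protocol; the acceptance
script and tests use 100 experiments, which resolves coverage to about
±0.05 Monte-Carlo error.

Two conventions needed fixing, and both repay discussion.

**What is "the true mean"?** The study scores, by default, each model's
genotype *seed-count estimate* — the inverse-link (or back-transformed)
genotype mean every analysis in this ladder reports — against the
generating count-component mean $\lambda_g$ (`truth = "component_mean"`).
Under this convention the models without an explicit zero process
(Gaussian, transformed, Poisson, NB) estimate the head-level mean
$(1-\pi_g)\lambda_g$ instead and are therefore systematically biased low
for $\lambda_g$; their intervals miss accordingly (catastrophically for
the transformed families, whose back-transformed means are biased even
for the head-level mean and whose delta-method standard errors are far too
small). The ZINB, which models the excess zeros explicitly, estimates
$\lambda_g$ consistently and keeps near-nominal coverage. The alternative
convention (`truth = "head_mean"`) scores intervals against
$(1-\pi_g)\lambda_g$, with the ZINB interval then built on its
inflation-adjusted mean; under that convention most models in the ladder
are consistent and coverage differences shrink to standard-error quality.
Only the component-mean convention reproduces the sharply stratified
pattern that motivates preferring mixture models on zero-inflated data,
and it is the default for that reason. The hurdle model is scored on its
reported $\lambda$ as well; note that because the positives of a
zero-inflated process are exactly zero-truncated NB, the hurdle's
$\hat\lambda$ is a consistent estimate of $\lambda_g$, so its coverage
stays near nominal here even though its inflation probability estimates
$\Pr(Y=0)$ rather than the structural-zero weight. In fact, with
per-genotype inflation the ZINB and HNB fits are reparameterizations of
the same fitted distribution — both saturate the per-genotype zero mass
and fit the identical zero-truncated NB likelihood to the positives — so
their seed-count intervals, and hence their coverage, coincide.

**Interval construction.** Count-family intervals are Wald intervals on
the link scale, back-transformed (so they respect positivity and are
order-preserved); transformed-Gaussian intervals are symmetric data-scale
intervals from delta-method standard errors, mirroring the analysis
practice whose failure this study quantifies — their lower bounds go
negative (a nonsensical seed count, flagged by
`genotype_count_means()`). Intervals from non-converged fits are excluded
from the denominator (the exclusion count is reported so the opposite
convention can be reconstructed); non-finite intervals from converged fits
count as non-coverage. Interval endpoints are inclusive; ties have
probability zero up to floating point.

The fitted models omit the whole-plot term (the study protocol drops
subsampling effects for computational efficiency) and, by default, the
block term too: the generating process carries no block heterogeneity, so
a block variance estimate just sits on its boundary; `include_block`
restores it.

Coverage magnitudes at these settings depend visibly on the per-genotype
sample size: the biased models' point estimates miss by a fixed relative
amount while their intervals shrink like $1/\sqrt{n}$, so with 20 heads
per genotype they retain partial coverage from interval width alone, and
increasing the heads per genotype drives their coverage toward zero. The
study's problem sizes (26 genotypes, 20 heads, 100 experiments in the
acceptance script; reduced further in unit tests) keep a full run in
minutes on one CPU.

## Known limitations

* Wald intervals and tests throughout; no profile likelihood or bootstrap.
  Near boundaries (inflation probabilities close to 0 or 1, complete
  separation) the intervals are clipped and flagged, not corrected.
* Combined across-year models are deliberately unsupported (the reference
  analysis abandoned them for non-convergence); fit seasons separately.
* The nested (block + whole-plot) quadrature is exact in structure but
  costs an inner integral per outer node; trial-sized nested binary fits
  take seconds, and large simulation studies should drop terms the design
  cannot identify anyway.
* Denominator-df rules for mixed-model F tests are approximations;
  both supported rules are documented above and the conservative behavior
  at small designs is measured in the test suite.
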