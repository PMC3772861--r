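---
title: "Interval-censored life-history analysis for common-garden cohort experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-censored life-history analysis for common-garden cohort experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitecohort)
```

## The experiment and its data

`mitecohort` analyses common-garden cohort experiments in which lines of an
arthropod (the motivating system is the Pacific spider mite on grapevine,
compared across source cultivars Zinfandel and Chardonnay) are reared on a
common host under identical conditions, and each assay population is
photographed at fixed intervals rather than handled. The observable data are
stage counts — eggs, immatures, adults — per assay population per sampling
day. The hierarchy matters: mites from one vineyard found a laboratory
*sample colony*; each colony founds several *assay populations* (cohorts of
10 eggs or of 5 mated females); colonies inherit a *cultivar* label from
their source vineyard. Any analysis of the cultivar effect must therefore
accommodate two nested levels of random variation, and development times are
only known up to the 2-day window between samples.

Three analysis datasets are derived from the counts:

* **Maturation intervals** (egg cohorts). If the adult count increased
  between two samples, immatures matured in that interval. Because adults
  can also die between samples, we count maturations as the positive
  increments of the *running maximum* of the adult count: a dip and
  recovery is attributed to an adult death followed by a genuinely new
  maturation, and no maturation is ever counted twice. Events observed
  first at day $d$ are assigned to the interval $(d-2,\,d]$.
* **Day-4 survival** (egg cohorts): individuals still visible (any stage)
  at day 4, out of the founding 10. Day 4 is late enough to capture early
  juvenile mortality and early enough that maturation has not begun to
  confound the count.
* **Day-2 fecundity** (adult cohorts): eggs present at day 2, with the
  number of females still alive at day 2 carried as a covariate for females
  that died before reproducing.

### Censoring policy

Individuals never observed as adults by day 12 are ambiguous: they may
still be developing, or they may have died as juveniles, and the photographs
cannot distinguish these fates individual by individual. The development
model deliberately has no mortality competing risk, so the package's default
(`policy = "censor-all"`) right-censors *all* never-matured individuals at
day 12 — the conservative completion of the interval-censored data. The
alternative `"drop-dead"` censors only individuals still visibly immature at
the last sample, dropping earlier disappearances from the risk set. The
choice is exposed because neither is derivable from the data; with
non-trivial juvenile mortality the two give genuinely different fitted
shapes (censor-all inflates the apparent late tail, dragging the Weibull
shape down), which is a property of the observation process, not a defect of
either fit.

### The day-6 dichotomy

The GLMM view of development condenses the intervals into "matured by day 6"
versus "matured later". The default denominator is the number of individuals
that matured at any time during the study, since the landmark partitions the
maturers; `denominator = "initial"` instead uses the founding cohort size,
counting never-matured individuals as failures. Assays in which nobody
matured carry zero trials and are dropped from the binomial fit with a
warning.

## The time-to-event model

Development times follow a Weibull law with survival function

$$S(t \mid i, j) = \exp\{-(\lambda_{ij}\, t)^k\}, \qquad
\log \lambda_{ij} = \log \lambda_0 + \beta\, x_{ij} + u_i + v_{ij},$$

with shape $k$ (dimensionless; $k > 1$ means the maturation hazard rises
with age), baseline rate $\lambda_0$ (1/day), cultivar indicator $x = 1$ for
Zinfandel (so $\beta > 0$ means faster development in Zinfandel-sourced
lines), and independent Normal random effects $u_i \sim N(0,
\sigma^2_{\text{colony}})$ and $v_{ij} \sim N(0, \sigma^2_{\text{assay}})$.
Covariates act multiplicatively on the rate — an accelerated-failure-time
parameterisation. The alternative convention $\exp(-\lambda t^k)$ differs
only by the rescaling $\lambda \to \lambda^k$; we fix the stated form and
effects on $\log \lambda$ throughout.

The conditional likelihood of one assay's data is the multinomial kernel of
its interval counts ($\sum_b m_b \log[S(l_b) - S(r_b)]$ plus the
right-censored mass at $\log S(12)$); the marginal likelihood integrates
this over the nested random effects,

$$L = \prod_i \int \phi(u;\sigma_c) \prod_{j \in i}
\left[ \int \phi(v;\sigma_a)\, e^{\ell_{ij}(u+v)}\, dv \right] du .$$

### Numerical choices

* **Quadrature.** Both integrals are evaluated with Gauss–Hermite rules of
  order 15 by default. The assay-level (inner) integral carries the weight
  of the data (10 individuals per assay) and is *mode-adaptive*: a short
  vectorised Newton iteration recentres and rescales the nodes at the
  integrand's mode. The colony-level (outer) integral uses prior-scaled
  nodes: its integrand is already smoothed by the inner integration, and
  colony-level variance in this design is small or zero. Degenerate levels
  ($\sigma = 0$) are evaluated exactly as point masses, so the marginal
  likelihood reduces *identically* to the fixed-effects likelihood at the
  boundary. The test suite validates the quadrature against brute-force
  Monte-Carlo integration ($10^6$ draws) on a two-colony toy; order 1 with
  adaptation is a Laplace approximation and is available for speed.
* **Parameterisation.** $k$ and $\lambda_0$ are optimized on the log scale;
  $\beta$ is unconstrained; the standard deviations are optimized on their
  natural scale with a lower bound at exactly 0 (not log-variance), so a
  zero variance component — which this design produces routinely at the
  colony level — is representable exactly and flagged as a boundary
  estimate.
* **Optimizer.** Bounded quasi-Newton (`L-BFGS-B`, likelihood tolerance
  $\approx 10^{-8}$) from moment-based starting values (Weibull moments of
  the interval midpoints), with optional jittered multi-starts (default 5
  for headline fits) drawn from a fixed internal substream so results do
  not depend on the caller's RNG state. GLMM coefficients get a final
  Newton polish, which makes the variance-pinned fits agree with `glm` to
  below $10^{-6}$.
* **Uncertainty.** The observed-information covariance is computed by
  central finite differences on the internal scale; variance components
  estimated on the boundary are excluded from the Hessian (their Wald
  theory fails there), and their rows are absent from `vcov`.
* **Fitted-curve bands.** `random_effect_band()` shifts $\log \lambda$ by
  quantiles (default 0.05/0.95) of the *combined* random-effect
  distribution $N(0, \sigma^2_{\text{colony}} + \sigma^2_{\text{assay}})$,
  displaying the envelope of assay-level curves around each cultivar's
  central fit.

## The companion GLMMs

The day-6 and day-4 analyses are binomial mixed models
($\text{logit}(p_{ij}) = \alpha + \beta_c x_i + u_i + v_{ij}$); fecundity is
a Poisson mixed model with the surviving-female count as a linear fixed
covariate ($\log \mu_{ij} = \alpha + \beta_c x_i + \gamma f_{ij} + u_i +
v_{ij}$; a log-offset variant is available). All three reuse the nested
quadrature engine, so the optimizer conventions, boundary handling and
pinning of variance components (`fix_sigma_* = 0`) are identical to the
time-to-event fit. Two points deserve emphasis:

* With one record per assay population, the assay intercept is an
  *observation-level* random effect. In the Poisson model it doubles as an
  overdispersion term; in both models it is weakly identified and often
  lands on the boundary. It is retained because it mirrors the stated
  model structure, not because the data demand it.
* Complete separation in the binomial model (e.g. every cohort fully
  matured) is flagged, and a lightly ridge-penalized fit is reported in its
  place with a warning.

`lme4::glmer` is used in the test suite as an independent cross-check of
the mixed binomial fit; since lme4 applies a Laplace approximation when two
random effects are present, agreement is asserted at the few-percent level
together with dominance of our adaptive-quadrature log-likelihood.

## Inference on the cultivar effect

Each analysis compares the full model against the null ($\beta_c = 0$) with
$D = 2\,\Delta\log L$. Two calibrations of $D$ are provided:

* the large-sample $\chi^2_1$ upper tail, and
* a **randomization test**: cultivar labels are permuted and both models
  refitted, $p = (1 + \#\{D_{\text{perm}} \ge D_{\text{obs}}\}) /
  (n_{\text{perm}} + 1)$ (the add-one form keeps $p > 0$). With 11
  colonies split 8/3 the label space has only $\binom{11}{3} = 165$
  distinct assignments, so an exhaustive mode enumerates them all and the
  sampled p-value converges to the exact one.

Permutation is at the **sample-colony level** by default — a colony's label
travels with all four of its assay populations — because colonies, not
assays, are the units exchangeable under the null in this hierarchy;
assay-level permutation is available as a sensitivity analysis. Variance
components are re-estimated in every permutation refit when
`mixed = TRUE`; the `mixed = FALSE` fitters pin them at zero, which makes
large permutation studies affordable (the pinned binomial refit is ordinary
logistic regression and is computed by IRLS). Permutation validity requires
only exchangeability of colony labels under the null, so the pinned fitters
give a valid, if slightly less powerful, test.

## The synthetic-data generator

The generator emulates the design the analysis assumes: 11 sample colonies
(8 Zinfandel, 3 Chardonnay), two egg cohorts of 10 and two adult cohorts of
5 per colony, sampled every 2 days for 12 days (7 occasions, 44 assay
populations, 22 of them egg-initiated). Its defaults are the study
conditions: Weibull shape 2.5, baseline rate 0.2/day, cultivar log-rate
effect 0.3, $\sigma_{\text{assay}} = 0.2$, $\sigma_{\text{colony}} = 0$;
day-4 juvenile survival 0.767 (Zinfandel) and 0.633 (Chardonnay); 10.8 eggs
per surviving female by day 2. One root seed drives everything, and each
colony and assay draws from a substream keyed by a stable hash of its
identifier, so enlarging the design never perturbs existing units.

Deliberate simplifications, and what they imply for the tests:

* Juvenile mortality is a single Bernoulli thinning per individual; death
  days (uniform before `min(maturation, 4)`) matter only for intermediate
  stage counts, never for any fitted quantity. There is no
  mortality–development interaction, so the generator cannot probe
  competing-risk bias.
* Egg hatching is rendered deterministically 2 days after laying, and
  adult-cohort egg laying is extended past day 2 at a constant Poisson rate
  purely to fill the series; only the day-2 egg count enters any analysis.
* No temperature dependence, no spatial structure, no gene flow, and adult
  females (beyond optional day-2 mortality) do not die. Passing tests
  therefore demonstrate correctness of the estimators under the model's own
  assumptions — not robustness to the many ways real cohort data violate
  them.

## Validation studies and their problem sizes

The package's statistical guarantees are asserted in the test suite at
sizes chosen to give each check real resolution while keeping a full run in
minutes:

* *Likelihood correctness*: nested quadrature within 0.5% of a
  $10^6$-draw Monte-Carlo oracle on a 2-colony/2-assay toy; exact
  ($<10^{-10}$) equality with the fixed-effects likelihood at
  $\sigma = 0$.
* *Parameter recovery*: 200 simulated experiments at the design scale and
  default parameters, fitted with order-7 adaptive quadrature and a single
  moment-based start (validated against higher-order fits). Recovery
  simulations set juvenile survival to 1: the development model has no
  mortality process, so its parameters are only well-defined targets under
  its own data-generating assumptions. Median relative bias of $\hat k$
  and $\hat\lambda_0$ is under 10%, Wald 95% coverage for $\beta$ lies in
  [0.90, 0.99], and $\hat\sigma_{\text{colony}}$ lands on the zero
  boundary in the majority of replicates.
* *Randomization calibration*: 200 null experiments with 199 colony-level
  permutations each, using the pinned-variance day-6 fitter (see above);
  empirical rejection at nominal 0.05 stays within [0.02, 0.09] — the
  small-sample distortion of the chi-squared approximation is exactly why
  the randomization test exists.
* *Exhaustive agreement*: the sampled 1000-draw p-value falls within 0.02
  of the exact 165-assignment enumeration on a null dataset, where the
  p-value is interior and the comparison is most stringent.

## Known limitations

* The Weibull family is fixed (the exponential arises at $k = 1$); no
  semi-parametric alternative, left truncation, or competing-risk
  mortality model is provided.
* Wald intervals for variance components near zero are unreliable;
  boundary estimates are flagged rather than tested.
* The observation-level assay effect in the GLMMs is weakly identified at
  this design size; its estimate, and consequently the split between
  colony and assay variance, should be read qualitatively.
* Randomization with `mixed = TRUE` refits the full marginal likelihood
  ~2000 times per analysis; plan for minutes, or use the pinned fitters.
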