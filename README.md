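# mitecohort

Life-history analysis for common-garden cohort experiments with
interval-censored observations.

Arthropod cohort experiments are often followed non-destructively: an assay
population founded from a known number of eggs or females is photographed at
fixed intervals, and only stage counts (eggs, immatures, adults) are
recorded. Development times are then *interval-censored* — a newly matured
individual is only known to have matured between two consecutive samples —
and the experimental hierarchy (source population → laboratory colony →
assay population) induces nested random variation. `mitecohort` implements
the full analysis chain for such designs, motivated by common-garden
comparisons of spider mite lines collected from different grapevine
cultivars (Zinfandel vs Chardonnay) and reared on a common bean host:

1. **Data reduction** — convert photographic stage counts into
   interval-censored maturation data (via the running maximum of the adult
   count, so adult deaths are never double-counted), a day-4 juvenile
   survival table, and a day-2 fecundity table.
2. **Mixed-effects Weibull time-to-event model** — maximum-likelihood fit
   of

   `S(t | i, j) = exp(−(λ_ij · t)^k)`,
   `log λ_ij = log λ₀ + β·x_ij + u_i + v_ij`,

   where `k` is the Weibull shape, `λ₀` the baseline rate (1/day), `β` the
   fixed cultivar effect on the log rate (`x = 1` for Zinfandel), and
   `u_i ~ N(0, σ²_colony)`, `v_ij ~ N(0, σ²_assay)` are nested random
   effects for sample colony and assay population. The marginal likelihood
   over interval-censored data is computed by nested (mode-adaptive)
   Gauss–Hermite quadrature; variance components are estimated on the
   standard-deviation scale with an exact zero boundary.
3. **Companion GLMMs** — binomial mixed models for maturation before day 6
   and survival to day 4, and a Poisson mixed model for day-2 egg counts
   with the number of surviving females as a fixed covariate, all fitted by
   the same adaptive-quadrature marginal likelihood.
4. **Inference** — likelihood-ratio tests of the cultivar effect with both
   the large-sample chi-squared approximation and a colony-level
   randomization null distribution (sampled, e.g. 1000 permutations, or
   exhaustive over all label assignments).
5. **Synthetic data** — a generator that emulates the hierarchical design
   (11 colonies: 8 Zinfandel + 3 Chardonnay; 2 egg cohorts of 10 and 2
   adult cohorts of 5 per colony; samples every 2 days for 12 days), so the
   whole pipeline runs and is tested without any external data.

## Worked example

```r
library(mitecohort)

cfg <- generator_config(seed = 42)            # the emulated design
counts <- simulate_experiment(cfg)            # 44 assay populations x 7 days
intervals <- derive_maturation_intervals(counts)

fit <- fit_weibull_frailty(intervals, model = "cultivar")
fit
#> Mixed-effects interval-censored Weibull fit (cultivar model)
#>   shape = 1.0678, rate0 = 0.0909/day, beta = 0.5571
#>   sigma_colony = 0.2206, sigma_assay = 0.1622
#>   log-likelihood = -376.5359 (converged)

null <- fit_weibull_frailty(intervals, model = "null")
lrt(fit, null, df = 1)
#> $D
#> [1] 4.478931
#> $p_chisq
#> [1] 0.03431519

day6 <- dichotomize_day6(intervals)
randomization_test(day6, binomial_lrt_fitter(mixed = FALSE),
                   n_perm = 999, seed = 1)
#> Randomization LRT (colony-level, sampled)
#>   D = 15.4563; p_chisq(df=1) = 8.443e-05; p_perm = 0.024 (999 permutations)
```

`beta = 0.557 > 0` means the Zinfandel-sourced lines develop faster (higher
log rate); the LRT compares the fits with and without that effect. The
randomization p-value (here 0.024) re-fits the day-6 model under 999
colony-level relabelings, giving a null distribution that does not rely on
the chi-squared large-sample approximation — note how much more
conservative it is than the chi-squared p on these 22 small cohorts.
`run_pipeline(pipeline_config(...))` performs every step above (plus the
survival and fecundity analyses) and writes CSV/JSON outputs with seed and
config provenance.

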