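#' Configuration for the synthetic common-garden generator
#'
#' Collects the experiment design and the generative parameters: Weibull
#' development times with survival function `S(t) = exp(-(lambda_ij t)^k)`,
#' where `log lambda_ij = log(rate0) + beta * [Zinfandel] + u_i + v_ij` with
#' independent Normal colony effects `u_i ~ N(0, sigma_colony^2)` and assay
#' effects `v_ij ~ N(0, sigma_assay^2)`; Bernoulli juvenile survival by
#' cultivar; and Poisson fecundity per surviving female.
#'
#' Defaults encode the study conditions the generator emulates: shape 2.5,
#' baseline rate 0.2/day, cultivar log-rate effect 0.3, assay-level sd 0.2,
#' no colony-level variation, day-4 juvenile survival 0.767 (Zinfandel) and
#' 0.633 (Chardonnay), and 10.8 eggs laid per female by day two.
#'
#' @param design an [experiment_design()].
#' @param shape Weibull shape `k` (> 0, dimensionless).
#' @param rate0 baseline Weibull rate `lambda0` (1/day) for the reference
#'   cultivar (Chardonnay).
#' @param beta cultivar effect on the log rate (1 = Zinfandel, so positive
#'   values mean faster development on Zinfandel-sourced lines).
#' @param sigma_colony,sigma_assay standard deviations (>= 0) of the colony
#'   and assay random effects on the log rate.
#' @param survival_zinfandel,survival_chardonnay probability a juvenile
#'   survives the juvenile period, by source cultivar.
#' @param eggs_per_female mean eggs laid per surviving female per sampling
#'   interval (the day-2 count is one interval's worth).
#' @param fecundity_beta cultivar effect (log scale) on the fecundity mean;
#'   0 by default (no cultivar effect on reproduction).
#' @param female_day2_survival probability an adult female survives to day 2.
#' @param seed integer root seed; all randomness in
#'   [simulate_experiment()] derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(design = experiment_design(),
                             shape = 2.5,
                             rate0 = 0.2,
                             beta = 0.3,
                             sigma_colony = 0,
                             sigma_assay = 0.2,
                             survival_zinfandel = 0.767,
                             survival_chardonnay = 0.633,
                             eggs_per_female = 10.8,
                             fecundity_beta = 0,
                             female_day2_survival = 1,
                             seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            shape > 0, rate0 > 0,
            sigma_colony >= 0, sigma_assay >= 0,
            survival_zinfandel >= 0, survival_zinfandel <= 1,
            survival_chardonnay >= 0, survival_chardonnay <= 1,
            eggs_per_female >= 0,
            female_day2_survival >= 0, female_day2_survival <= 1)
  structure(list(design = design, shape = shape, rate0 = rate0, beta = beta,
                 sigma_colony = sigma_colony, sigma_assay = sigma_assay,
                 survival_zinfandel = survival_zinfandel,
                 survival_chardonnay = survival_chardonnay,
                 eggs_per_female = eggs_per_female,
                 fecundity_beta = fecundity_beta,
                 female_day2_survival = female_day2_survival,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic 31-bit string hash; used to derive per-unit RNG substreams so
# that adding colonies/assays never perturbs existing ones
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

substream_seed <- function(root, id) {
  as.integer((stable_hash(id) + (root %% 2147483647) * 10007) %% 2147483647)
}

# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_substream <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw Weibull development times
#'
#' i.i.d. egg-to-adult development times with survival function
#' `S(t) = exp(-(rate * t)^shape)` (scale parameter `1/rate`).
#'
#' @param n number of individuals.
#' @param shape Weibull shape (> 0).
#' @param rate Weibull rate (> 0, 1/day).
#' @return Numeric vector of `n` event days.
#' @export
simulate_development_times <- function(n, shape, rate) {
  stopifnot(n >= 0, is.finite(shape), is.finite(rate))
  if (shape <= 0 || rate <= 0) stop("shape and rate must be positive")
  rweibull(n, shape = shape, scale = 1 / rate)
}

#' Draw colony and assay random effects
#'
#' Normal log-rate deviations for every colony (`u_i`) and every assay
#' population (`v_ij`) of the design, deterministically derived from the
#' config seed via per-unit substreams.
#'
#' @param config a [generator_config()].
#' @return A list with named vectors `colony` and `assay`, and the helper
#'   data frame `assays` (assay_id, colony_id, cultivar, cohort_type).
#' @export
sample_random_effects <- function(config) {
  d <- config$design
  u <- vapply(d$colonies$colony_id, function(id)
    with_substream(substream_seed(config$seed, paste0("colony:", id)),
                   rnorm(1, 0, config$sigma_colony)),
    numeric(1))
  assays <- assay_table(d)
  v <- vapply(assays$assay_id, function(id)
    with_substream(substream_seed(config$seed, paste0("assay:", id)),
                   rnorm(1, 0, config$sigma_assay)),
    numeric(1))
  list(colony = u, assay = v, assays = assays)
}

# enumerate the assay populations of a design
assay_table <- function(design) {
  rows <- lapply(seq_len(nrow(design$colonies)), function(i) {
    cid <- design$colonies$colony_id[i]
    cul <- design$colonies$cultivar[i]
    type <- rep(c("egg", "adult"),
                c(design$egg_cohorts, design$adult_cohorts))
    idx <- c(seq_len(design$egg_cohorts), seq_len(design$adult_cohorts))
    data.frame(assay_id = sprintf("%s-%s%d", cid,
                                  ifelse(type == "egg", "E", "A"), idx),
               colony_id = cid, cultivar = cul, cohort_type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bin individual event days into an observed cohort count series
#'
#' Applies the observation process to a vector of true maturation days:
#' each individual independently survives the juvenile period with
#' probability `survival_p` (non-survivors never appear as adults and
#' disappear from the juvenile counts at a uniformly drawn death day before
#' `min(maturation, death_window)`); survivors are first counted as adults at
#' the first sampling day at or after their event day. Eggs hatch into
#' immatures after a fixed 2-day egg stage (a cosmetic stage split only).
#'
#' @param event_days true maturation days (>= 0).
#' @param design an [experiment_design()].
#' @param survival_p juvenile survival probability.
#' @param death_window latest possible juvenile death day (default 4).
#' @return A data frame with columns `day`, `eggs`, `immatures`, `adults`,
#'   `cum_deaths`; at every day `eggs + immatures + adults + cum_deaths`
#'   equals the cohort size.
#' @export
censor_to_intervals <- function(event_days, design, survival_p = 1,
                                death_window = 4) {
  stopifnot(all(event_days >= 0), survival_p >= 0, survival_p <= 1)
  n <- length(event_days)
  days <- sampling_days(design)
  survives <- if (n) runif(n) < survival_p else logical(0)
  death_day <- rep(Inf, n)
  nd <- which(!survives)
  if (length(nd))
    death_day[nd] <- runif(length(nd)) * pmin(event_days[nd], death_window)
  egg_stage <- 2  # fixed egg duration, first rendered at the next sample day
  out <- lapply(days, function(d) {
    adults <- sum(survives & event_days <= d)
    dead <- sum(death_day <= d)
    alive_juv <- n - adults - dead
    eggs <- if (d < egg_stage) alive_juv else 0L
    data.frame(day = d, eggs = eggs, immatures = alive_juv - eggs,
               adults = adults, cum_deaths = dead)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a full common-garden experiment
#'
#' Generates one long-format cohort count table with the full hierarchical
#' structure: colony and assay random effects on the log development rate,
#' Weibull development times and Bernoulli juvenile survival for egg cohorts,
#' and Poisson egg laying for adult cohorts. Deterministic given
#' `config$seed`; each assay population draws from its own RNG substream.
#'
#' @param config a [generator_config()].
#' @param return_truth if `TRUE`, attach the latent random effects and the
#'   per-assay true event days as attributes `"random_effects"` and
#'   `"event_times"`.
#' @return A validated cohort count data frame (see [read_cohort_counts()]).
#' @examples
#' counts <- simulate_experiment(generator_config(seed = 42))
#' length(unique(counts$assay_id))   # 44 assay populations
#' @export
simulate_experiment <- function(config, return_truth = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  d <- config$design
  re <- sample_random_effects(config)
  assays <- re$assays
  days <- sampling_days(d)
  truth <- list()
  rows <- lapply(seq_len(nrow(assays)), function(i) {
    a <- assays[i, ]
    seed_i <- substream_seed(config$seed, paste0("obs:", a$assay_id))
    lam <- config$rate0 * exp(config$beta * cultivar_indicator(a$cultivar) +
                              re$colony[[a$colony_id]] +
                              re$assay[[a$assay_id]])
    with_substream(seed_i, {
      if (a$cohort_type == "egg") {
        tt <- simulate_development_times(d$egg_cohort_size, config$shape, lam)
        p <- if (a$cultivar == "Zinfandel") config$survival_zinfandel
             else config$survival_chardonnay
        ser <- censor_to_intervals(tt, d, survival_p = p)
        truth[[a$assay_id]] <<- tt
        data.frame(assay_id = a$assay_id, colony_id = a$colony_id,
                   cultivar = a$cultivar, cohort_type = "egg",
                   day = ser$day, eggs = ser$eggs, immatures = ser$immatures,
                   adults = ser$adults, stringsAsFactors = FALSE)
      } else {
        nf <- d$adult_cohort_size
        f2 <- rbinom(1, nf, config$female_day2_survival)
        mu <- config$eggs_per_female *
          exp(config$fecundity_beta * cultivar_indicator(a$cultivar))
        # eggs laid per sampling interval by the surviving females; laying
        # extended at the same rate after day 2 purely to fill the series
        laid <- rpois(length(days) - 1, mu * f2)
        laid_by <- c(0, cumsum(laid))
        hatched_by <- c(0, laid_by[seq_len(length(days) - 1)])
        data.frame(assay_id = a$assay_id, colony_id = a$colony_id,
                   cultivar = a$cultivar, cohort_type = "adult",
                   day = days, eggs = laid_by - hatched_by,
                   immatures = hatched_by,
                   adults = c(nf, rep(f2, length(days) - 1)),
                   stringsAsFactors = FALSE)
      }
    })
  })
  counts <- validate_cohort_counts(
    do.call(rbind, c(rows, list(make.row.names = FALSE))))
  if (return_truth) {
    attr(counts, "random_effects") <- re[c("colony", "assay")]
    attr(counts, "event_times") <- truth
  }
  counts
}
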