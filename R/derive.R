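#' Derive interval-censored maturation data from egg-cohort counts
#'
#' Maturation events are not observed directly: the photographs give adult
#' counts every `sample_interval` days, so a newly matured individual is only
#' known to have matured somewhere in the interval `(d - interval, d]` ending
#' at the first day `d` it was counted as an adult. Because adults can also
#' die between samples, the number maturing in an interval is inferred from
#' the positive increments of the *running maximum* of the adult count, which
#' never double-counts a maturation when the adult count dips and recovers.
#'
#' Individuals never observed as adults are handled by the censoring policy:
#' \describe{
#'   \item{`"censor-all"`}{all of them (including any that died as juveniles)
#'     are right-censored at the end of the study. The development model has
#'     no mortality competing risk, so this is the conservative completion of
#'     the interval-censored data. Default.}
#'   \item{`"drop-dead"`}{only individuals still alive and immature at the
#'     last sample (`eggs + immatures` on the final day) are right-censored;
#'     individuals that disappeared earlier are dropped from the risk set.}
#' }
#'
#' @param counts validated long-format cohort counts
#'   (see [read_cohort_counts()]); only `cohort_type == "egg"` rows are used.
#' @param policy right-censoring policy, see Details.
#' @return A data frame with one row per assay x interval: `assay_id`,
#'   `colony_id`, `cultivar`, `lower`, `upper`, `matured`, and the per-assay
#'   constant `right_censored`. The attribute `study_length` records the last
#'   sampling day.
#' @examples
#' counts <- simulate_experiment(generator_config(seed = 1))
#' iv <- derive_maturation_intervals(counts)
#' head(iv)
#' @export
derive_maturation_intervals <- function(counts,
                                        policy = c("censor-all", "drop-dead")) {
  policy <- match.arg(policy)
  counts <- validate_cohort_counts(counts)
  eggs <- counts[counts$cohort_type == "egg", , drop = FALSE]
  if (!nrow(eggs)) stop("no egg-cohort rows in counts")
  res <- lapply(split_assays(eggs), function(a) {
    if (a$adults[1] > 0)
      stop("assay ", a$assay_id[1],
           ": egg cohort has adults at the first sample")
    initial <- a$eggs[1] + a$immatures[1] + a$adults[1]
    rm_ <- cummax(a$adults)
    matured <- diff(rm_)                       # maturations per interval
    if (sum(matured) > initial)
      stop("assay ", a$assay_id[1],
           ": more maturations than founding individuals")
    cens <- switch(policy,
                   "censor-all" = initial - sum(matured),
                   "drop-dead" = a$eggs[length(a$day)] +
                                 a$immatures[length(a$day)])
    data.frame(assay_id = a$assay_id[1],
               colony_id = a$colony_id[1],
               cultivar = a$cultivar[1],
               lower = a$day[-length(a$day)],
               upper = a$day[-1],
               matured = matured,
               right_censored = cens,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "study_length") <- max(out$upper)
  out
}

#' Dichotomize maturation intervals at a landmark day
#'
#' Condenses interval-censored maturation data into a binomial outcome:
#' individuals that matured on or before the landmark day versus those that
#' matured later. By convention the denominator is the number of individuals
#' that matured at any time during the study (the landmark partitions the
#' maturers); `denominator = "initial"` instead uses the founding cohort
#' size, counting never-matured individuals as failures.
#'
#' @param intervals output of [derive_maturation_intervals()].
#' @param landmark landmark day; must be an interval boundary.
#' @param denominator `"matured"` (default) or `"initial"`.
#' @return A data frame with columns `assay_id`, `colony_id`, `cultivar`,
#'   `successes`, `trials`. Assays where `trials == 0` are retained here but
#'   dropped (with a warning) by the binomial fitters.
#' @export
dichotomize_day6 <- function(intervals, landmark = 6,
                             denominator = c("matured", "initial")) {
  denominator <- match.arg(denominator)
  if (!landmark %in% intervals$upper)
    stop("landmark day ", landmark, " is not an interval boundary")
  res <- lapply(split(intervals, intervals$assay_id), function(a) {
    tot <- sum(a$matured)
    data.frame(assay_id = a$assay_id[1],
               colony_id = a$colony_id[1],
               cultivar = a$cultivar[1],
               successes = sum(a$matured[a$upper <= landmark]),
               trials = if (denominator == "matured") tot
                        else tot + a$right_censored[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Derive day-4 juvenile survival from egg-cohort counts
#'
#' Survivors at the landmark day are everything still visible in the cohort
#' (eggs + immatures + adults, capped at the founding size); the landmark is
#' chosen early enough that essentially no individual has matured, so the
#' count reflects juvenile survival rather than development.
#'
#' @inheritParams derive_maturation_intervals
#' @param day landmark day; must be a sampling day for every egg cohort.
#' @return A data frame with columns `assay_id`, `colony_id`, `cultivar`,
#'   `successes` (alive at `day`), `trials` (founding cohort size).
#' @export
derive_survival_day4 <- function(counts, day = 4) {
  counts <- validate_cohort_counts(counts)
  eggs <- counts[counts$cohort_type == "egg", , drop = FALSE]
  if (!nrow(eggs)) stop("no egg-cohort rows in counts")
  res <- lapply(split_assays(eggs), function(a) {
    i <- match(day, a$day)
    if (is.na(i))
      stop("assay ", a$assay_id[1], ": day ", day, " is not a sampling day")
    initial <- a$eggs[1] + a$immatures[1] + a$adults[1]
    alive <- min(a$eggs[i] + a$immatures[i] + a$adults[i], initial)
    data.frame(assay_id = a$assay_id[1],
               colony_id = a$colony_id[1],
               cultivar = a$cultivar[1],
               successes = alive,
               trials = initial,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Derive day-2 fecundity from adult-cohort counts
#'
#' Early reproductive output of the adult cohorts: the number of eggs present
#' at the landmark day, together with the number of females still alive then
#' (used downstream as a fixed covariate to account for females that died
#' before reproducing).
#'
#' @inheritParams derive_maturation_intervals
#' @param day landmark day; must be a sampling day for every adult cohort.
#' @return A data frame with columns `assay_id`, `colony_id`, `cultivar`,
#'   `eggs_day2`, `surviving_females_day2`.
#' @export
derive_fecundity_day2 <- function(counts, day = 2) {
  counts <- validate_cohort_counts(counts)
  ad <- counts[counts$cohort_type == "adult", , drop = FALSE]
  if (!nrow(ad)) stop("no adult-cohort rows in counts")
  res <- lapply(split_assays(ad), function(a) {
    i <- match(day, a$day)
    if (is.na(i))
      stop("assay ", a$assay_id[1], ": day ", day, " is not a sampling day")
    data.frame(assay_id = a$assay_id[1],
               colony_id = a$colony_id[1],
               cultivar = a$cultivar[1],
               eggs_day2 = a$eggs[i],
               surviving_females_day2 = a$adults[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
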