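#' Likelihood-ratio test of nested fits
#'
#' `D = 2 (loglik_full - loglik_null)`, clipped at zero (small negative
#' values up to `tolerance` are attributed to optimizer noise; larger ones
#' are an error), with an upper-tail chi-squared p-value.
#'
#' @param full,null fitted model objects with a `loglik` element (or bare
#'   numeric log-likelihoods).
#' @param df degrees of freedom (number of parameters dropped in the null).
#' @param tolerance largest tolerated negative `D` before erroring.
#' @return A list with `D`, `df`, `p_chisq`.
#' @examples
#' lrt(2, 0, df = 1)   # D = 4, p ~ 0.0455
#' @export
lrt <- function(full, null, df = 1, tolerance = 1e-4) {
  ll_f <- if (is.numeric(full)) full else full$loglik
  ll_n <- if (is.numeric(null)) null else null$loglik
  D <- 2 * (ll_f - ll_n)
  if (D < -tolerance)
    stop("null model has higher likelihood than the full model (D = ",
         signif(D, 4), "); refit with more starts")
  D <- max(D, 0)
  list(D = D, df = df, p_chisq = pchisq(D, df = df, lower.tail = FALSE))
}

#' Enumerate cultivar label assignments over colonies
#'
#' All distinct ways to assign the minority cultivar label to `n_minority`
#' of the colonies (the exact-test companion to sampled randomization).
#' Guarded against combinatorial blow-up at 1e6 assignments.
#'
#' @param colonies character vector of colony ids.
#' @param n_minority number of colonies carrying the minority label.
#' @return A list of character vectors (the colonies assigned the minority
#'   label), of length `choose(length(colonies), n_minority)`.
#' @export
enumerate_label_assignments <- function(colonies, n_minority) {
  n <- length(colonies)
  stopifnot(n_minority >= 0, n_minority <= n)
  if (choose(n, n_minority) > 1e6)
    stop("more than 1e6 assignments; use sampled randomization")
  sets <- combn(n, n_minority, simplify = FALSE)
  lapply(sets, function(i) colonies[i])
}

# relabel a dataset's cultivar column according to a colony -> cultivar map
relabel_cultivar <- function(data, minority_colonies, labels) {
  data$cultivar <- ifelse(data$colony_id %in% minority_colonies,
                          labels["minority"], labels["majority"])
  data
}

#' Randomization test of the cultivar effect
#'
#' Builds a null distribution for the likelihood-ratio statistic `D` by
#' permuting cultivar labels and refitting the full and null models. Labels
#' are permuted at the sample-colony level by default (a colony's label
#' travels with all its assay populations), preserving the hierarchical
#' structure and the observed label split; `level = "assay"` permutes at the
#' assay level as a sensitivity analysis. The p-value includes the observed
#' statistic: `p = (1 + #{D_perm >= D_obs}) / (n_perm + 1)`. With
#' `exhaustive = TRUE` all distinct colony-label assignments are evaluated
#' instead and `p = mean(D_all >= D_obs)` (the observed assignment is one of
#' them).
#'
#' @param data analysis dataset with `colony_id` and `cultivar` columns
#'   (interval data, binary outcome data, or fecundity data).
#' @param fitter function `(data) -> D` returning the likelihood-ratio
#'   statistic of the cultivar effect on a dataset; see
#'   [weibull_lrt_fitter()], [binomial_lrt_fitter()],
#'   [poisson_lrt_fitter()].
#' @param n_perm number of sampled permutations.
#' @param seed integer seed for the permutation draw (required for
#'   reproducibility).
#' @param level permutation unit, `"colony"` (default) or `"assay"`.
#' @param exhaustive enumerate all label assignments instead of sampling
#'   (colony level only).
#' @param max_fail_frac abort if more than this fraction of permutation
#'   refits fail.
#' @return A list of class `randomization_test` with `D_obs`, `p_perm`,
#'   `p_chisq`, `df`, `n_perm` (effective), `null_distribution`,
#'   `n_failed`, `exhaustive`.
#' @export
randomization_test <- function(data, fitter, n_perm = 1000, seed = 1L,
                               level = c("colony", "assay"),
                               exhaustive = FALSE, max_fail_frac = 0.05) {
  level <- match.arg(level)
  stopifnot(n_perm >= 1)
  D_obs <- fitter(data)
  cmap <- unique(data[, c("colony_id", "cultivar")])
  tab <- sort(table(cmap$cultivar))
  if (length(tab) != 2)
    stop("randomization needs two observed cultivar labels")
  labels <- c(minority = names(tab)[1], majority = names(tab)[2])
  fit_one <- function(d)
    tryCatch(suppressWarnings(fitter(d)), error = function(e) NA_real_)
  if (exhaustive) {
    if (level != "colony") stop("exhaustive mode is colony-level only")
    assigns <- enumerate_label_assignments(cmap$colony_id, tab[1])
    D_null <- vapply(assigns, function(mino)
      fit_one(relabel_cultivar(data, mino, labels)), numeric(1))
    keep <- !is.na(D_null)
    if (mean(!keep) > max_fail_frac)
      stop("more than ", 100 * max_fail_frac, "% of refits failed")
    D_null <- D_null[keep]
    p_perm <- mean(D_null >= D_obs - 1e-12)
    n_eff <- length(D_null)
  } else {
    units <- if (level == "colony") cmap$colony_id else
      unique(data$assay_id)
    n_min <- if (level == "colony") tab[1] else {
      amap <- unique(data[, c("assay_id", "cultivar")])
      sum(amap$cultivar == labels["minority"])
    }
    perm_sets <- with_substream(as.integer(seed %% 2147483647),
      lapply(seq_len(n_perm), function(i) sample(units, n_min)))
    D_null <- vapply(perm_sets, function(mino) {
      d <- if (level == "colony") relabel_cultivar(data, mino, labels)
      else {
        d2 <- data
        d2$cultivar <- ifelse(d2$assay_id %in% mino,
                              labels["minority"], labels["majority"])
        d2
      }
      fit_one(d)
    }, numeric(1))
    keep <- !is.na(D_null)
    if (mean(!keep) > max_fail_frac)
      stop("more than ", 100 * max_fail_frac, "% of permutation refits failed")
    D_null <- D_null[keep]
    n_eff <- length(D_null)
    p_perm <- (1 + sum(D_null >= D_obs - 1e-12)) / (n_eff + 1)
  }
  structure(list(D_obs = D_obs, df = 1,
                 p_chisq = pchisq(D_obs, df = 1, lower.tail = FALSE),
                 p_perm = p_perm, n_perm = n_eff,
                 null_distribution = D_null,
                 n_failed = sum(!keep), exhaustive = exhaustive,
                 level = level),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, ...) {
  cat(sprintf("Randomization LRT (%s-level, %s)\n", x$level,
              if (x$exhaustive) "exhaustive" else "sampled"))
  cat(sprintf("  D = %.4f; p_chisq(df=1) = %.4g; p_perm = %.4g (%d %s)\n",
              x$D_obs, x$p_chisq, x$p_perm, x$n_perm,
              if (x$exhaustive) "assignments" else "permutations"))
  invisible(x)
}

#' Likelihood-ratio fitters for randomization tests
#'
#' Factories returning `(data) -> D` functions that refit the full
#' (cultivar) and null models and return the likelihood-ratio statistic.
#' `mixed = FALSE` pins both variance components at zero, giving the much
#' faster fixed-effects refit used for large permutation studies; variance
#' components are otherwise re-estimated in every refit.
#'
#' @param mixed re-estimate random-effect standard deviations per refit.
#' @param quad_order,adapt,n_starts settings passed to the underlying fit.
#' @param females_as passed to [fit_poisson_glmm()].
#' @return A function mapping a dataset to the LRT statistic `D`.
#' @export
weibull_lrt_fitter <- function(mixed = TRUE, quad_order = 7, adapt = TRUE,
                               n_starts = 1) {
  fs <- if (mixed) NULL else 0
  function(data) {
    f <- fit_weibull_frailty(data, "cultivar", quad_order, adapt, n_starts,
                             fix_sigma_colony = fs, fix_sigma_assay = fs,
                             se = FALSE)
    n <- fit_weibull_frailty(data, "null", quad_order, adapt, n_starts,
                             fix_sigma_colony = fs, fix_sigma_assay = fs,
                             se = FALSE)
    max(2 * (f$loglik - n$loglik), 0)
  }
}

#' @rdname weibull_lrt_fitter
#' @export
binomial_lrt_fitter <- function(mixed = TRUE, quad_order = 7, adapt = TRUE,
                                n_starts = 1) {
  if (!mixed) {
    # with both variance components pinned at 0 the model is ordinary
    # logistic regression; refit by IRLS, D = deviance difference
    return(function(data) {
      data <- data[data$trials > 0, , drop = FALSE]
      y <- data$successes / data$trials
      x <- cultivar_indicator(data$cultivar)
      f <- stats::glm.fit(cbind(1, x), y, weights = data$trials,
                          family = stats::binomial())
      n <- stats::glm.fit(matrix(1, nrow(data)), y, weights = data$trials,
                          family = stats::binomial())
      max(n$deviance - f$deviance, 0)
    })
  }
  function(data) {
    data <- data[data$trials > 0, , drop = FALSE]
    f <- fit_glmm(data, "binomial", "cultivar", quad_order = quad_order,
                  adapt = adapt, n_starts = n_starts, se = FALSE)
    n <- fit_glmm(data, "binomial", "null", quad_order = quad_order,
                  adapt = adapt, n_starts = n_starts, se = FALSE)
    max(2 * (f$loglik - n$loglik), 0)
  }
}

#' @rdname weibull_lrt_fitter
#' @export
poisson_lrt_fitter <- function(mixed = TRUE, females_as = "covariate",
                               quad_order = 7, adapt = TRUE, n_starts = 1) {
  fs <- if (mixed) NULL else 0
  function(data) {
    f <- fit_poisson_glmm(data, "cultivar", females_as, quad_order, adapt,
                          n_starts, fix_sigma_colony = fs,
                          fix_sigma_assay = fs, se = FALSE)
    n <- fit_poisson_glmm(data, "null", females_as, quad_order, adapt,
                          n_starts, fix_sigma_colony = fs,
                          fix_sigma_assay = fs, se = FALSE)
    max(2 * (f$loglik - n$loglik), 0)
  }
}
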