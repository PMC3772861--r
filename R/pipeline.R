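#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: input (a counts CSV or
#' generate-mode), output directory, seeds, landmarks, censoring policy,
#' quadrature order, and the number of randomization permutations. Can also
#' be read from a YAML file whose keys mirror the arguments (the `generator`
#' key holds [generator_config()] arguments).
#'
#' @param counts_csv path to a long-format counts CSV, or `NULL` to generate
#'   synthetic data from `generator`.
#' @param out_dir output directory (created if missing); `NULL` returns
#'   results without writing files.
#' @param generator a [generator_config()] used when `counts_csv` is `NULL`.
#' @param seed root seed for permutation draws (and recorded in outputs).
#' @param n_perm randomization permutations per analysis; 0 skips the
#'   randomization tests (chi-squared p-values only).
#' @param perm_mixed re-estimate variance components in permutation refits
#'   (`TRUE`, slow but the full procedure) or pin them at zero for speed.
#' @param quad_order,adapt quadrature settings for the model fits.
#' @param n_starts optimizer multi-starts for the headline fits.
#' @param day6,day4,day2 landmark days for the three derived datasets.
#' @param censoring right-censoring policy, see
#'   [derive_maturation_intervals()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_csv = NULL, out_dir = NULL,
                            generator = generator_config(),
                            seed = 1L, n_perm = 1000, perm_mixed = TRUE,
                            quad_order = 15, adapt = TRUE, n_starts = 5,
                            day6 = 6, day4 = 4, day2 = 2,
                            censoring = c("censor-all", "drop-dead")) {
  structure(list(counts_csv = counts_csv, out_dir = out_dir,
                 generator = generator, seed = as.integer(seed),
                 n_perm = n_perm, perm_mixed = perm_mixed,
                 quad_order = quad_order, adapt = adapt,
                 n_starts = n_starts,
                 day6 = day6, day4 = day4, day2 = day2,
                 censoring = match.arg(censoring)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with pipeline configuration keys.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$colonies))
    gen_args$design <- experiment_design(
      colonies = do.call(rbind, lapply(gen_args$colonies, as.data.frame)))
  gen_args$colonies <- NULL
  y$generator <- do.call(generator_config, gen_args)
  do.call(pipeline_config, y)
}

# small hash of the analysis-relevant configuration (output location
# excluded) for output provenance
config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL
  s <- paste(deparse(c2), collapse = "")
  sprintf("%08x", stable_hash(s))
}

#' Run the full analysis pipeline
#'
#' Reads (or generates) cohort counts, derives the three analysis datasets
#' (maturation intervals, day-4 survival, day-2 fecundity), fits the
#' mixed-effects Weibull model and the three GLMMs with and without the
#' cultivar effect, and tests the cultivar effect by chi-squared and
#' (optionally) colony-level randomization LRTs. Results are returned as a
#' list and, when `out_dir` is set, written as CSVs and JSON files; byte
#' identical on rerun with the same config and seed.
#'
#' @param config a [pipeline_config()].
#' @return A list with elements `counts`, `datasets`, `fits`, `tests`,
#'   `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- if (is.null(config$counts_csv)) {
    simulate_experiment(config$generator)
  } else read_cohort_counts(config$counts_csv)

  intervals <- derive_maturation_intervals(counts, policy = config$censoring)
  day6 <- dichotomize_day6(intervals, landmark = config$day6)
  survival <- derive_survival_day4(counts, day = config$day4)
  fecundity <- derive_fecundity_day2(counts, day = config$day2)
  datasets <- list(intervals = intervals, day6 = day6,
                   survival = survival, fecundity = fecundity)

  qo <- config$quad_order; ad <- config$adapt; ns <- config$n_starts
  fits <- list(
    tte_cultivar = fit_weibull_frailty(intervals, "cultivar", qo, ad, ns),
    tte_null = fit_weibull_frailty(intervals, "null", qo, ad, ns),
    day6_cultivar = fit_binomial_glmm(day6, "cultivar", qo, ad, ns),
    day6_null = fit_binomial_glmm(day6, "null", qo, ad, ns),
    survival_cultivar = fit_binomial_glmm(survival, "cultivar", qo, ad, ns),
    survival_null = fit_binomial_glmm(survival, "null", qo, ad, ns),
    fecundity_cultivar = fit_poisson_glmm(fecundity, "cultivar",
                                          quad_order = qo, adapt = ad,
                                          n_starts = ns),
    fecundity_null = fit_poisson_glmm(fecundity, "null",
                                      quad_order = qo, adapt = ad,
                                      n_starts = ns))

  analyses <- list(
    development_tte = list(full = "tte_cultivar", null = "tte_null",
                           data = "intervals",
                           fitter = weibull_lrt_fitter(config$perm_mixed)),
    development_day6 = list(full = "day6_cultivar", null = "day6_null",
                            data = "day6",
                            fitter = binomial_lrt_fitter(config$perm_mixed)),
    survival_day4 = list(full = "survival_cultivar", null = "survival_null",
                         data = "survival",
                         fitter = binomial_lrt_fitter(config$perm_mixed)),
    fecundity_day2 = list(full = "fecundity_cultivar",
                          null = "fecundity_null", data = "fecundity",
                          fitter = poisson_lrt_fitter(config$perm_mixed)))
  tests <- lapply(names(analyses), function(nm) {
    an <- analyses[[nm]]
    base <- lrt(fits[[an$full]], fits[[an$null]], df = 1)
    out <- list(analysis = nm, D = base$D, df = 1, p_chisq = base$p_chisq,
                p_perm = NA_real_, n_perm = 0L)
    if (config$n_perm > 0) {
      rt <- randomization_test(datasets[[an$data]], an$fitter,
                               n_perm = config$n_perm,
                               seed = substream_seed(config$seed,
                                                     paste0("perm:", nm)))
      out$p_perm <- rt$p_perm
      out$n_perm <- rt$n_perm
      out$null_distribution <- rt$null_distribution
    }
    out
  })
  names(tests) <- names(analyses)

  summary <- list(
    seed = config$seed, config_hash = config_hash(config),
    n_assay_populations = length(unique(counts$assay_id)),
    n_egg_assays = length(unique(counts$assay_id[
      counts$cohort_type == "egg"])),
    analyses = lapply(tests, function(t) {
      beta <- if (t$analysis == "development_tte")
        fits$tte_cultivar$params[["beta"]]
      else fits[[analyses[[t$analysis]]$full]]$coefficients[
        "cultivarZinfandel"]
      list(D = t$D, p_chisq = t$p_chisq, p_perm = t$p_perm,
           cultivar_effect = unname(beta),
           direction = if (is.na(beta)) NA_character_
                       else if (beta > 0) "higher on Zinfandel"
                       else "higher on Chardonnay")
    }))

  res <- list(counts = counts, datasets = datasets, fits = fits,
              tests = tests, summary = summary)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

fit_to_list <- function(fit) {
  if (inherits(fit, "wf_fit")) {
    list(params = as.list(fit$params), loglik = fit$loglik,
         converged = fit$converged, boundary = as.list(fit$boundary),
         se = as.list(fit$se %||% list()),
         vcov = fit$vcov,
         n_obs = as.list(fit$n_obs), model = fit$model)
  } else {
    list(coefficients = as.list(fit$coefficients),
         sigma = as.list(fit$sigma), loglik = fit$loglik,
         converged = fit$converged, boundary = as.list(fit$boundary),
         separation = fit$separation,
         se = as.list(fit$se %||% list()),
         family = fit$family, model = fit$model)
  }
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character(0)
  on.exit(if (!ok) unlink(written))
  wcsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  wjson <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    header <- list(seed = config$seed, config_hash = config_hash(config),
                   schema_version = "1.0")
    jsonlite::write_json(c(header, obj), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    written <<- c(written, path)
  }
  wcsv(res$counts, "counts.csv")
  wcsv(res$datasets$intervals, "intervals.csv")
  wcsv(res$datasets$day6, "day6.csv")
  wcsv(res$datasets$survival, "survival.csv")
  wcsv(res$datasets$fecundity, "fecundity.csv")
  for (nm in names(res$fits))
    wjson(fit_to_list(res$fits[[nm]]), paste0("fit_", nm, ".json"))
  for (nm in names(res$tests))
    wjson(res$tests[[nm]], paste0("test_", nm, ".json"))
  wjson(res$summary, "summary.json")
  ok <- TRUE
  invisible(res)
}
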