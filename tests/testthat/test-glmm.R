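test_that("variance-pinned mixed fits equal their GLM counterparts", {
  cfg <- generator_config(seed = 11, female_day2_survival = 0.9)
  counts <- simulate_experiment(cfg)
  sv <- derive_survival_day4(counts)
  ours <- fit_binomial_glmm(sv, "cultivar", fix_sigma_colony = 0,
                            fix_sigma_assay = 0, n_starts = 1, se = FALSE)
  oracle <- stats::glm(cbind(successes, trials - successes) ~
                         cultivar_ind, binomial,
                       data = transform(sv,
                         cultivar_ind = as.integer(cultivar == "Zinfandel")))
  expect_equal(unname(ours$coefficients), unname(coef(oracle)),
               tolerance = 1e-7)
  expect_equal(ours$loglik, as.numeric(logLik(oracle)), tolerance = 1e-9)

  fc <- derive_fecundity_day2(counts)
  oursp <- fit_poisson_glmm(fc, "cultivar", fix_sigma_colony = 0,
                            fix_sigma_assay = 0, n_starts = 1, se = FALSE)
  oraclep <- stats::glm(eggs_day2 ~ cultivar_ind + surviving_females_day2,
                        poisson,
                        data = transform(fc,
                          cultivar_ind = as.integer(cultivar == "Zinfandel")))
  expect_equal(unname(oursp$coefficients), unname(coef(oraclep)),
               tolerance = 1e-7)
})

test_that("the mixed binomial fit agrees with lme4 on the same data", {
  cfg <- generator_config(seed = 19, sigma_assay = 0.4)
  counts <- simulate_experiment(cfg)
  d6 <- dichotomize_day6(derive_maturation_intervals(counts))
  d6 <- d6[d6$trials > 0, ]
  ours <- fit_binomial_glmm(d6, "cultivar", quad_order = 15, n_starts = 2,
                            se = FALSE)
  lme4_fit <- lme4::glmer(
    cbind(successes, trials - successes) ~ cultivar_ind +
      (1 | colony_id) + (1 | assay_id),
    data = transform(d6, cultivar_ind = as.integer(cultivar == "Zinfandel")),
    family = stats::binomial())
  # lme4 uses a Laplace approximation for two random effects; our adaptive
  # quadrature differs slightly on this flat likelihood but must attain at
  # least as high a marginal log-likelihood
  expect_equal(unname(ours$coefficients),
               unname(lme4::fixef(lme4_fit)), tolerance = 0.06)
  expect_gte(ours$loglik, as.numeric(logLik(lme4_fit)) - 0.01)
})

test_that("degenerate binomial data are flagged", {
  # all successes: complete separation on the intercept scale
  allwin <- data.frame(assay_id = paste0("a", 1:8),
                       colony_id = rep(c("Z1", "Z2", "C1", "C2"), each = 2),
                       cultivar = rep(c("Zinfandel", "Chardonnay"), each = 4),
                       successes = 10, trials = 10)
  expect_warning(
    fit <- fit_binomial_glmm(allwin, "cultivar", fix_sigma_colony = 0,
                             fix_sigma_assay = 0, n_starts = 1, se = FALSE),
    "separation")
  expect_true(fit$separation)
  # zero-trial rows are dropped with a warning
  d <- allwin
  d$successes <- c(5, 6, 7, 8, 4, 5, 6, 7)
  d$trials[3] <- 0; d$successes[3] <- 0
  expect_warning(fit2 <- fit_binomial_glmm(d, "cultivar",
                                           fix_sigma_colony = 0,
                                           fix_sigma_assay = 0,
                                           n_starts = 1, se = FALSE),
                 "zero-trial")
  expect_equal(fit2$n_obs, 7)
})

test_that("Poisson mean scaling shifts only the intercept", {
  cfg <- generator_config(seed = 23, female_day2_survival = 0.9)
  fc <- derive_fecundity_day2(simulate_experiment(cfg))
  f1 <- fit_poisson_glmm(fc, "cultivar", fix_sigma_colony = 0,
                         fix_sigma_assay = 0, n_starts = 1, se = FALSE)
  fc2 <- fc
  fc2$eggs_day2 <- 3 * fc$eggs_day2
  f3 <- fit_poisson_glmm(fc2, "cultivar", fix_sigma_colony = 0,
                         fix_sigma_assay = 0, n_starts = 1, se = FALSE)
  expect_equal(f3$coefficients[["(Intercept)"]] -
               f1$coefficients[["(Intercept)"]], log(3), tolerance = 1e-4)
  expect_equal(f3$coefficients[["cultivarZinfandel"]],
               f1$coefficients[["cultivarZinfandel"]], tolerance = 1e-3)
})

test_that("cultivar effect is centred at zero under null fecundity", {
  betas <- sapply(1:20, function(seed) {
    fc <- derive_fecundity_day2(simulate_experiment(
      generator_config(seed = 300 + seed, fecundity_beta = 0)))
    suppressWarnings(fit_poisson_glmm(fc, "cultivar", quad_order = 5,
                     n_starts = 1, se = FALSE))$coefficients[[
                       "cultivarZinfandel"]]
  })
  expect_lt(abs(mean(betas)), 3 * stats::sd(betas) / sqrt(length(betas)) +
            0.02)
})

test_that("the females offset variant drops zero-female rows", {
  cfg <- generator_config(seed = 29, female_day2_survival = 0.5,
                          design = small_design())
  fc <- derive_fecundity_day2(simulate_experiment(cfg))
  fc$surviving_females_day2[1] <- 0
  expect_warning(fit <- fit_poisson_glmm(fc, "cultivar",
                                         females_as = "offset",
                                         fix_sigma_colony = 0,
                                         fix_sigma_assay = 0,
                                         n_starts = 1, se = FALSE),
                 "zero-female")
  oracle <- stats::glm(eggs_day2 ~ cultivar_ind,
                       offset = log(surviving_females_day2), poisson,
                       data = transform(fc[fc$surviving_females_day2 > 0, ],
                         cultivar_ind = as.integer(cultivar == "Zinfandel")))
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
})

test_that("the chi-squared LRT is roughly calibrated at design scale", {
  # null simulations at the full hierarchical design; mild boundary and
  # small-sample distortion is expected (and motivates the randomization
  # test), but the type-I error should stay near nominal
  fitter <- binomial_lrt_fitter(mixed = TRUE, quad_order = 5, n_starts = 1)
  Ds <- sapply(1:500, function(i) {
    d6 <- dichotomize_day6(derive_maturation_intervals(simulate_experiment(
      generator_config(seed = 40000 + i, beta = 0))))
    suppressWarnings(fitter(d6))
  })
  rate <- mean(pchisq(Ds, 1, lower.tail = FALSE) <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.09)
})
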