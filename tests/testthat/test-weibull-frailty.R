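test_that("the Weibull survival function matches closed forms", {
  expect_equal(weibull_survival(1, shape = 1, rate = log(2)), 0.5)
  expect_equal(weibull_survival(2, shape = 2, rate = 0.5), exp(-1))
  expect_equal(weibull_survival(0, shape = 3.7, rate = 0.01), 1)
  expect_true(all(diff(weibull_survival(0:10, 2, 0.3)) < 0))
  expect_error(weibull_survival(-1, 1, 1), "non-negative")
})

test_that("interval log-likelihood is the multinomial log-kernel", {
  one <- data.frame(assay_id = "a", colony_id = "c", cultivar = "Zinfandel",
                    lower = 0, upper = 1, matured = 1, right_censored = 0)
  expect_equal(interval_log_likelihood(one, shape = 1, rate = log(2)),
               log(0.5))
  # brute-force multinomial oracle on a 3-interval partition + censoring
  iv <- toy_intervals()[1:3, ]
  k <- 2.2; lam <- 0.21
  p <- surv_oracle(iv$lower, k, lam) - surv_oracle(iv$upper, k, lam)
  expected <- sum(iv$matured * log(p)) +
    iv$right_censored[1] * log(surv_oracle(6, k, lam))
  expect_equal(interval_log_likelihood(iv, k, lam), expected)
  # the interval probabilities and the censoring mass form a partition
  expect_equal(sum(p) + surv_oracle(6, k, lam), 1)
  # zero-probability interval with a count is impossible
  imp <- data.frame(assay_id = "a", colony_id = "c", cultivar = "Zinfandel",
                    lower = c(0, 50), upper = c(50, 51),
                    matured = c(9, 1), right_censored = 0)
  expect_identical(interval_log_likelihood(imp, 3, 1), -Inf)
  # empty data: log of an empty product
  expect_equal(interval_log_likelihood(one[0, ], 2, 0.2), 0)
})

test_that("marginal likelihood degenerates exactly when sigmas vanish", {
  toy <- toy_intervals()
  params <- list(shape = 2, rate0 = 0.2, beta = 0.3,
                 sigma_colony = 0, sigma_assay = 0)
  fe <- sum(sapply(split(toy, toy$assay_id), function(a)
    interval_log_likelihood(a, 2,
      0.2 * exp(0.3 * (a$cultivar[1] == "Zinfandel")))))
  expect_equal(weibull_marginal_loglik(params, toy), fe, tolerance = 1e-12)
  # doubling every count doubles the log-likelihood only without frailty
  toy2 <- toy
  toy2$matured <- 2 * toy$matured
  toy2$right_censored <- 2 * toy$right_censored
  expect_equal(weibull_marginal_loglik(params, toy2), 2 * fe,
               tolerance = 1e-12)
  pf <- utils::modifyList(params, list(sigma_assay = 0.4))
  expect_gt(abs(weibull_marginal_loglik(pf, toy2) -
                2 * weibull_marginal_loglik(pf, toy)), 0.01)
})

test_that("marginal likelihood is invariant to relabeling colonies", {
  toy <- toy_intervals()
  params <- list(shape = 2, rate0 = 0.2, beta = 0.3,
                 sigma_colony = 0.25, sigma_assay = 0.3)
  ll <- weibull_marginal_loglik(params, toy)
  relabeled <- toy
  relabeled$colony_id <- chartr("AB", "QP", toy$colony_id)
  relabeled$assay_id <- paste0("x", toy$assay_id)
  expect_equal(weibull_marginal_loglik(params, relabeled), ll,
               tolerance = 1e-10)
})

test_that("quadrature converges with order toward a Monte-Carlo oracle", {
  toy <- toy_intervals()
  params <- list(shape = 2, rate0 = 0.2, beta = 0.3,
                 sigma_colony = 0.3, sigma_assay = 0.3)
  # independent MC oracle over (u, v_j) via direct pweibull
  set.seed(4)
  n <- 2e5
  mc_colony <- function(block, x) {
    u <- rnorm(n, 0, params$sigma_colony)
    tot <- rep(0, n)
    for (a in block) {
      v <- rnorm(n, 0, params$sigma_assay)
      lam <- params$rate0 * exp(params$beta * x + u + v)
      li <- a$right_censored[1] * log(surv_oracle(max(a$upper), 2, lam))
      for (r in seq_len(nrow(a)))
        li <- li + a$matured[r] *
          log(surv_oracle(a$lower[r], 2, lam) - surv_oracle(a$upper[r], 2, lam))
      tot <- tot + li
    }
    m <- max(tot)
    log(mean(exp(tot - m))) + m
  }
  mc <- mc_colony(split(toy[1:6, ], toy$assay_id[1:6]), 1) +
        mc_colony(split(toy[7:12, ], toy$assay_id[7:12]), 0)
  errs <- sapply(c(3, 7, 15), function(q)
    abs(weibull_marginal_loglik(params, toy, quad_order = q) - mc))
  expect_lt(errs[3], 0.01 * abs(mc))
  expect_lt(errs[3], errs[1] + 1e-6)
  # adaptive and prior-scaled quadrature agree at high order
  expect_equal(weibull_marginal_loglik(params, toy, 25, adapt = TRUE),
               weibull_marginal_loglik(params, toy, 25, adapt = FALSE),
               tolerance = 1e-6)
})

test_that("fixed-effects MLE matches a brute-force grid-search oracle", {
  design <- small_design(n_z = 6, n_c = 6, egg_cohorts = 4,
                         egg_cohort_size = 25)
  cfg <- generator_config(design = design, sigma_colony = 0, sigma_assay = 0,
                          survival_zinfandel = 1, survival_chardonnay = 1,
                          seed = 21)
  iv <- derive_maturation_intervals(simulate_experiment(cfg))
  fit <- fit_weibull_frailty(iv, "cultivar", fix_sigma_colony = 0,
                             fix_sigma_assay = 0, n_starts = 2, se = FALSE)
  # oracle: two-stage profile grid over (shape, rate0, beta) on the
  # fixed-effects likelihood assembled from interval_log_likelihood
  byassay <- split(iv, iv$assay_id)
  fe_ll <- function(k, l0, b) sum(vapply(byassay, function(a)
    interval_log_likelihood(a, k,
      l0 * exp(b * (a$cultivar[1] == "Zinfandel"))), numeric(1)))
  centre <- c(2.5, 0.2, 0.3)
  for (span in c(0.35, 0.04, 0.005)) {
    gk <- centre[1] * seq(1 - span, 1 + span, length.out = 13)
    gl <- centre[2] * seq(1 - span, 1 + span, length.out = 13)
    gb <- centre[3] + seq(-span, span, length.out = 13)
    grid <- expand.grid(k = gk, l = gl, b = gb)
    vals <- mapply(fe_ll, grid$k, grid$l, grid$b)
    centre <- unlist(grid[which.max(vals), ], use.names = FALSE)
  }
  expect_equal(fit$params[["shape"]], centre[1], tolerance = 2e-3)
  expect_equal(fit$params[["rate0"]], centre[2], tolerance = 2e-3)
  expect_equal(fit$params[["beta"]], centre[3], tolerance = 2e-2)
})

test_that("full and null fits nest and converge on simulated data", {
  cfg <- generator_config(seed = 31, survival_zinfandel = 1,
                          survival_chardonnay = 1)
  iv <- derive_maturation_intervals(simulate_experiment(cfg))
  full <- fit_weibull_frailty(iv, "cultivar", quad_order = 7, n_starts = 1)
  null <- fit_weibull_frailty(iv, "null", quad_order = 7, n_starts = 1)
  expect_true(full$converged && null$converged)
  expect_gte(full$loglik, null$loglik - 1e-6)
  expect_equal(null$params[["beta"]], 0)
  # vcov of the free parameters is symmetric positive semidefinite
  expect_true(isSymmetric(full$vcov, tol = 1e-8))
  expect_true(all(eigen(full$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_error(fit_weibull_frailty(iv[iv$cultivar == "Zinfandel", ],
                                   "cultivar"), "both cultivars")
})

test_that("random-effect bands shift the log rate by Normal quantiles", {
  cfg <- generator_config(seed = 31, survival_zinfandel = 1,
                          survival_chardonnay = 1)
  iv <- derive_maturation_intervals(simulate_experiment(cfg))
  fit <- fit_weibull_frailty(iv, "cultivar", quad_order = 7, n_starts = 1)
  band <- random_effect_band(fit, 0.05, 0.95, times = c(2, 5, 8))
  sig <- sqrt(fit$params[["sigma_colony"]]^2 + fit$params[["sigma_assay"]]^2)
  for (cu in c("Zinfandel", "Chardonnay")) {
    lam <- fit$params[["rate0"]] *
      exp(fit$params[["beta"]] * (cu == "Zinfandel"))
    up <- band[band$cultivar == cu & band$band == "upper", ]
    expect_equal(up$survival,
                 weibull_survival(up$time, fit$params[["shape"]],
                                  lam * exp(qnorm(0.95) * sig)),
                 tolerance = 1e-12)
    # bands bracket the central curve pointwise (higher rate = faster)
    ce <- band[band$cultivar == cu & band$band == "central", ]
    lo <- band[band$cultivar == cu & band$band == "lower", ]
    expect_true(all(up$survival <= ce$survival & ce$survival <= lo$survival))
  }
  # degenerate random effects collapse the bands onto the central curve
  f0 <- fit_weibull_frailty(iv, "cultivar", fix_sigma_colony = 0,
                            fix_sigma_assay = 0, n_starts = 1, se = FALSE)
  b0 <- random_effect_band(f0, times = c(3, 6))
  expect_equal(b0$survival[b0$band == "upper"],
               b0$survival[b0$band == "central"])
  expect_error(random_effect_band(list()), "wf_fit")
})
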