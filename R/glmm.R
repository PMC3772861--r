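# Binomial and Poisson mixed models with colony and assay random intercepts,
# fitted by the same nested Gauss-Hermite marginal likelihood as the Weibull
# frailty model. The assay intercept is observation-level for these datasets
# (one record per assay population) and in the Poisson model doubles as an
# overdispersion term; its estimate may legitimately hit the zero boundary.

fit_glmm <- function(data, family, model, covariate = NULL, offset = NULL,
                     quad_order = 15, adapt = TRUE, n_starts = 5,
                     fix_sigma_colony = NULL, fix_sigma_assay = NULL,
                     se = TRUE) {
  x <- cultivar_indicator(data$cultivar)
  if (model == "cultivar" && length(unique(x)) < 2)
    stop("cultivar model needs records from both cultivars")
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (model == "cultivar") X <- cbind(X, cultivarZinfandel = x)
  if (!is.null(covariate)) X <- cbind(X, females = covariate)
  const <- c(FALSE, apply(X[, -1, drop = FALSE], 2,
                          function(cc) length(unique(cc)) == 1))
  if (any(const)) {
    warning("dropping constant column(s) from the design matrix: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (is.null(offset)) offset <- numeric(n)
  colony <- data$colony_id
  if (family == "binomial") {
    succ <- data$successes; trials <- data$trials
    make_ll <- function(coefs) {
      eta <- as.vector(X %*% coefs) + offset
      function(off) matrix(dbinom(succ, trials, plogis(eta + off),
                                  log = TRUE), n)
    }
    a0 <- stats::qlogis(min(max(sum(succ) / sum(trials), 0.02), 0.98))
  } else {
    yy <- data$eggs_day2
    make_ll <- function(coefs) {
      eta <- as.vector(X %*% coefs) + offset
      function(off) matrix(dpois(yy, exp(eta + off), log = TRUE), n)
    }
    a0 <- log(max(mean(yy / exp(offset)), 0.5))
  }
  p_coef <- ncol(X)
  free_sig <- c(sigma_colony = is.null(fix_sigma_colony),
                sigma_assay = is.null(fix_sigma_assay))
  sig_fix <- c(sigma_colony = fix_sigma_colony %||% 0,
               sigma_assay = fix_sigma_assay %||% 0)
  unpack <- function(theta) {
    coefs <- theta[seq_len(p_coef)]
    sig <- sig_fix
    sig[names(free_sig)[free_sig]] <- theta[-seq_len(p_coef)]
    list(coefs = coefs, sig = pmax(sig, 0))
  }
  negll <- function(theta) {
    u <- unpack(theta)
    val <- nested_marginal_loglik(make_ll(u$coefs), colony,
                                  u$sig[["sigma_colony"]],
                                  u$sig[["sigma_assay"]], quad_order, adapt)
    if (!is.finite(val)) 1e10 else -val
  }
  th0 <- c(a0, rep(0, p_coef - 1), rep(0.1, sum(free_sig)))
  names(th0) <- c(colnames(X), names(free_sig)[free_sig])
  lower <- c(rep(-Inf, p_coef), rep(0, sum(free_sig)))
  starts <- list(th0)
  if (n_starts > 1) {
    starts <- c(starts, with_substream(
      substream_seed(20130913L, paste0("glmm-", family)),
      lapply(seq_len(n_starts - 1), function(i)
        pmax(th0 + rnorm(length(th0), 0, 0.5), lower))))
  }
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(optim(s0, negll, method = "L-BFGS-B", lower = lower,
                        control = list(factr = 4.5e7, maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  # Newton polish of the regression coefficients (variance components held
  # at their estimates) to sharpen coefficient precision
  theta <- newton_polish_coefs(negll, theta, p_coef)
  u <- unpack(theta)
  loglik <- -negll(theta)
  separation <- FALSE
  if (family == "binomial" && any(abs(u$coefs) > 10)) {
    separation <- TRUE
    pen_negll <- function(th) negll(th) + 1e-2 * sum(th[seq_len(p_coef)]^2)
    o <- tryCatch(optim(th0, pen_negll, method = "L-BFGS-B", lower = lower,
                        control = list(factr = 4.5e7, maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(o)) {
      theta <- o$par
      u <- unpack(theta)
      loglik <- -negll(theta)
    }
    warning("possible complete separation; penalized fit reported")
  }
  boundary <- free_sig & u$sig[names(free_sig)] < 1e-4
  V <- NULL
  if (se) {
    keep <- c(rep(TRUE, p_coef), !boundary[free_sig])
    V <- fd_vcov(function(tf) {
      t2 <- theta; t2[keep] <- tf
      -negll(t2)
    }, theta[keep])
  }
  pe <- predict_random_effects(make_ll(u$coefs), colony,
                               u$sig[["sigma_colony"]],
                               u$sig[["sigma_assay"]], quad_order, adapt)
  names(pe$assay) <- data$assay_id
  structure(list(coefficients = setNames(u$coefs, colnames(X)),
                 sigma = u$sig, loglik = loglik,
                 converged = best$convergence == 0,
                 boundary = boundary, free_sigma = free_sig,
                 separation = separation,
                 vcov = V$vcov, se = V$se,
                 predicted_effects = pe,
                 family = family, model = model, n_obs = n),
            class = "glmm_fit")
}

newton_polish_coefs <- function(negll, theta, p_coef, iter = 3) {
  idx <- seq_len(p_coef)
  for (it in seq_len(iter)) {
    g <- numeric(p_coef)
    H <- matrix(0, p_coef, p_coef)
    h <- pmax(abs(theta[idx]), 0.1) * 1e-5
    f0 <- negll(theta)
    if (!is.finite(f0) || f0 >= 1e10) return(theta)
    for (i in idx) {
      ei <- numeric(length(theta)); ei[i] <- h[i]
      fp <- negll(theta + ei); fm <- negll(theta - ei)
      g[i] <- (fp - fm) / (2 * h[i])
      H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
    }
    for (i in idx) for (j in idx) if (j > i) {
      ei <- ej <- numeric(length(theta))
      ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (negll(theta + ei + ej) - negll(theta + ei - ej) -
         negll(theta - ei + ej) + negll(theta - ei - ej)) /
        (4 * h[i] * h[j])
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(theta)
    cand <- theta
    cand[idx] <- theta[idx] - step
    if (negll(cand) <= f0) theta <- cand else return(theta)
    if (max(abs(step)) < 1e-9) break
  }
  theta
}

#' Fit a binomial mixed model for a dichotomized cohort outcome
#'
#' Logistic regression of per-assay successes/trials on the source cultivar
#' with Normal random intercepts for sample colony and assay population,
#' `logit(p_ij) = alpha + beta_c x_i + u_i + v_ij`, fitted by adaptive
#' Gauss-Hermite marginal likelihood. Used for the probability of maturing
#' before day 6 and the probability of surviving to day 4. Zero-trial rows
#' are dropped with a warning. Complete separation is flagged and a
#' ridge-penalized fit reported.
#'
#' @param data data frame with columns `assay_id`, `colony_id`, `cultivar`,
#'   `successes`, `trials` (see [dichotomize_day6()],
#'   [derive_survival_day4()]).
#' @param model `"cultivar"` or `"null"` (drops the cultivar effect).
#' @param quad_order,adapt quadrature settings.
#' @param n_starts optimizer starts.
#' @param fix_sigma_colony,fix_sigma_assay optionally pin a random-effect
#'   standard deviation (0 gives ordinary logistic regression).
#' @param se compute the observed-information covariance.
#' @return An object of class `glmm_fit`: `coefficients`, `sigma`, `loglik`,
#'   `converged`, `boundary`, `separation`, `vcov`, `predicted_effects`.
#' @export
fit_binomial_glmm <- function(data, model = c("cultivar", "null"),
                              quad_order = 15, adapt = TRUE, n_starts = 5,
                              fix_sigma_colony = NULL,
                              fix_sigma_assay = NULL, se = TRUE) {
  model <- match.arg(model)
  drop <- data$trials == 0
  if (any(drop)) {
    warning(sum(drop), " zero-trial row(s) dropped from binomial fit")
    data <- data[!drop, , drop = FALSE]
  }
  if (!nrow(data)) stop("no usable rows (all zero trials)")
  fit_glmm(data, "binomial", model, quad_order = quad_order, adapt = adapt,
           n_starts = n_starts, fix_sigma_colony = fix_sigma_colony,
           fix_sigma_assay = fix_sigma_assay, se = se)
}

#' Fit a Poisson mixed model for early fecundity
#'
#' Log-linear regression of the day-2 egg count on source cultivar and the
#' number of surviving females (a fixed covariate accounting for females
#' that died before reproducing), with colony and assay random intercepts:
#' `log(mu_ij) = alpha + beta_c x_i + gamma f_ij + u_i + v_ij`. The assay
#' intercept is observation-level and absorbs overdispersion.
#'
#' @param data data frame with columns `assay_id`, `colony_id`, `cultivar`,
#'   `eggs_day2`, `surviving_females_day2` (see [derive_fecundity_day2()]).
#' @param females_as `"covariate"` (linear fixed effect, default) or
#'   `"offset"` (log offset).
#' @inheritParams fit_binomial_glmm
#' @return An object of class `glmm_fit`.
#' @export
fit_poisson_glmm <- function(data, model = c("cultivar", "null"),
                             females_as = c("covariate", "offset"),
                             quad_order = 15, adapt = TRUE, n_starts = 5,
                             fix_sigma_colony = NULL,
                             fix_sigma_assay = NULL, se = TRUE) {
  model <- match.arg(model)
  females_as <- match.arg(females_as)
  if (all(data$eggs_day2 == 0)) stop("all egg counts are zero")
  if (females_as == "offset") {
    keep <- data$surviving_females_day2 > 0
    if (!all(keep)) warning(sum(!keep), " zero-female row(s) dropped")
    data <- data[keep, , drop = FALSE]
    return(fit_glmm(data, "poisson", model,
                    offset = log(data$surviving_females_day2),
                    quad_order = quad_order, adapt = adapt,
                    n_starts = n_starts,
                    fix_sigma_colony = fix_sigma_colony,
                    fix_sigma_assay = fix_sigma_assay, se = se))
  }
  fit_glmm(data, "poisson", model,
           covariate = data$surviving_females_day2,
           quad_order = quad_order, adapt = adapt, n_starts = n_starts,
           fix_sigma_colony = fix_sigma_colony,
           fix_sigma_assay = fix_sigma_assay, se = se)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("%s mixed model (%s), AGQ marginal likelihood\n",
              tools::toTitleCase(x$family), x$model))
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma_colony = %.4f%s, sigma_assay = %.4f%s\n",
              x$sigma[["sigma_colony"]],
              if (isTRUE(x$boundary[["sigma_colony"]])) " (boundary)" else "",
              x$sigma[["sigma_assay"]],
              if (isTRUE(x$boundary[["sigma_assay"]])) " (boundary)" else ""))
  cat(sprintf("  log-likelihood = %.4f%s%s\n", x$loglik,
              if (x$converged) "" else " (NOT converged)",
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' @export
logLik.glmm_fit <- function(object, ...) {
  df <- length(object$coefficients) + sum(object$free_sigma)
  structure(object$loglik, df = df, class = "logLik")
}

#' @export
coef.glmm_fit <- function(object, ...) object$coefficients
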