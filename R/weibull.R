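#' Weibull survival function
#'
#' `S(t) = exp(-(rate * t)^shape)`: the probability that an individual's
#' development time exceeds `t` days.
#'
#' @param t time in days (>= 0).
#' @param shape Weibull shape (> 0).
#' @param rate Weibull rate (> 0, 1/day).
#' @return Survival probabilities, same length as `t`.
#' @examples
#' weibull_survival(1, shape = 1, rate = log(2))   # 0.5
#' @export
weibull_survival <- function(t, shape, rate) {
  stopifnot(shape > 0, rate > 0)
  if (any(t < 0)) stop("t must be non-negative")
  exp(-(rate * t)^shape)
}

#' Interval-censored Weibull log-likelihood for one assay population
#'
#' Multinomial log-kernel of interval-censored maturation counts:
#' `sum_b matured_b * log(S(lower_b) - S(upper_b)) +
#'  right_censored * log(S(max(upper)))`. Returns `-Inf` when an interval
#' with zero probability carries a nonzero count; empty data gives 0.
#'
#' @param intervals data frame with columns `lower`, `upper`, `matured` and
#'   (constant) `right_censored`, as one assay's rows from
#'   [derive_maturation_intervals()].
#' @param shape,rate Weibull parameters for this assay.
#' @return Scalar log-likelihood.
#' @export
interval_log_likelihood <- function(intervals, shape, rate) {
  if (!nrow(intervals)) return(0)
  stopifnot(all(intervals$lower < intervals$upper))
  p <- weibull_survival(intervals$lower, shape, rate) -
       weibull_survival(intervals$upper, shape, rate)
  cens <- intervals$right_censored[1]
  s_end <- weibull_survival(max(intervals$upper), shape, rate)
  terms <- c(ifelse(intervals$matured > 0, intervals$matured * log(p), 0),
             if (cens > 0) cens * log(s_end) else 0)
  if (any(intervals$matured > 0 & p <= 0)) return(-Inf)
  sum(terms)
}

# internal matrix form of interval data for the quadrature engine
interval_matrices <- function(intervals) {
  sp <- split(intervals, intervals$assay_id)
  breaks <- sort(unique(intervals$upper))
  cm <- vapply(sp, function(a) {
    cnt <- numeric(length(breaks))
    cnt[match(a$upper, breaks)] <- a$matured
    cnt
  }, numeric(length(breaks)))
  counts <- if (is.matrix(cm)) t(cm) else matrix(cm, ncol = 1)
  info <- do.call(rbind, lapply(sp, function(a)
    data.frame(assay_id = a$assay_id[1], colony_id = a$colony_id[1],
               cultivar = a$cultivar[1], right_censored = a$right_censored[1],
               stringsAsFactors = FALSE)))
  bad <- !mapply(function(a) all(a$lower %in% c(0, breaks)), sp)
  if (any(bad)) stop("interval partitions must share a common break grid")
  list(counts = counts, breaks = breaks, cens = info$right_censored,
       info = info)
}

# factory: per-assay conditional log-likelihood as a function of a log-rate
# offset matrix (n_assay x M)
make_weibull_assay_ll <- function(m, eta, log_shape) {
  k <- exp(log_shape)
  n <- nrow(m$counts)
  B <- length(m$breaks)
  counts <- m$counts
  breaks <- m$breaks
  cens <- m$cens
  function(offsets) {
    M <- ncol(offsets)
    lam <- as.vector(exp(eta + offsets))           # n*M, assay fastest
    S <- exp(-(lam %o% breaks)^k)                  # (n*M) x B
    p <- cbind(1, S[, -B, drop = FALSE]) - S
    logp <- log(pmax(p, 1e-300))
    ce <- counts[rep(seq_len(n), M), , drop = FALSE]
    ll <- rowSums(ce * logp) +
      cens[rep(seq_len(n), M)] * log(pmax(S[, B], 1e-300))
    matrix(ll, n, M)
  }
}

#' Marginal log-likelihood of the mixed-effects Weibull model
#'
#' Integrates the interval-censored Weibull likelihood over the nested
#' Normal colony and assay random effects on the log rate by nested
#' Gauss-Hermite quadrature (mode-adaptive at the assay level). With both
#' standard deviations zero this reduces exactly to the fixed-effects
#' log-likelihood.
#'
#' @param params named list or vector with elements `shape`, `rate0`,
#'   `beta`, `sigma_colony`, `sigma_assay`.
#' @param intervals interval data for all egg-cohort assays
#'   (see [derive_maturation_intervals()]).
#' @param quad_order Gauss-Hermite order per level (>= 1).
#' @param adapt recentre the assay-level quadrature at the integrand mode.
#' @return Scalar marginal log-likelihood.
#' @export
weibull_marginal_loglik <- function(params, intervals, quad_order = 15,
                                    adapt = TRUE) {
  p <- as.list(params)
  stopifnot(p$shape > 0, p$rate0 > 0,
            p$sigma_colony >= 0, p$sigma_assay >= 0, quad_order >= 1)
  m <- interval_matrices(intervals)
  eta <- log(p$rate0) + p$beta * cultivar_indicator(m$info$cultivar)
  ll <- make_weibull_assay_ll(m, eta, log(p$shape))
  nested_marginal_loglik(ll, m$info$colony_id, p$sigma_colony,
                         p$sigma_assay, quad_order, adapt)
}

# crude moment-based starting values from interval midpoints
weibull_start <- function(m) {
  mids <- (c(0, m$breaks[-length(m$breaks)]) + m$breaks) / 2
  tot_m <- sum(m$counts)
  if (tot_m == 0) stop("all individuals right-censored; cannot fit")
  w <- colSums(m$counts)
  mu <- sum(w * mids) / tot_m
  s2 <- sum(w * (mids - mu)^2) / max(tot_m - 1, 1)
  cv2 <- max(s2, 1e-4) / mu^2
  k <- tryCatch(uniroot(function(k)
    gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2,
    c(0.3, 50))$root, error = function(e) 1.5)
  c(log_shape = log(k), log_rate0 = log(gamma(1 + 1 / k) / mu),
    beta = 0)
}

#' Fit the mixed-effects interval-censored Weibull model
#'
#' Maximum-likelihood fit of the Weibull frailty model
#' `S(t | i, j) = exp(-(lambda_ij t)^shape)` with
#' `log lambda_ij = log(rate0) + beta * [Zinfandel] + u_i + v_ij`,
#' `u_i ~ N(0, sigma_colony^2)` (sample colony) and `v_ij ~ N(0,
#' sigma_assay^2)` (assay population). Shape and baseline rate are optimized
#' on the log scale; the standard deviations on their natural scale with a
#' lower bound at 0, so boundary estimates (zero variance components) are
#' representable exactly. `model = "null"` fixes `beta = 0`.
#'
#' @param intervals output of [derive_maturation_intervals()].
#' @param model `"cultivar"` (full model) or `"null"` (no cultivar effect).
#' @param quad_order,adapt quadrature settings, see
#'   [weibull_marginal_loglik()].
#' @param n_starts number of optimizer starts (1 deterministic start from
#'   moment-based initials plus `n_starts - 1` jittered restarts drawn from
#'   a fixed substream).
#' @param fix_sigma_colony,fix_sigma_assay optionally pin a variance
#'   component's standard deviation at a given value (e.g. 0 for a
#'   fixed-effects fit).
#' @param se compute the observed-information covariance of the free
#'   parameters (internal scale) by central finite differences; variance
#'   components estimated on the boundary are excluded.
#' @param start optional named starting vector on the internal scale
#'   (`log_shape`, `log_rate0`, `beta`, `sigma_colony`, `sigma_assay`).
#' @return An object of class `wf_fit` with elements `params` (natural
#'   scale), `loglik`, `converged`, `boundary`, `vcov`, `se`,
#'   `predicted_effects`, `n_obs`, `model`.
#' @examples
#' counts <- simulate_experiment(generator_config(seed = 7))
#' iv <- derive_maturation_intervals(counts)
#' fit <- fit_weibull_frailty(iv, quad_order = 7, n_starts = 1)
#' fit
#' @export
fit_weibull_frailty <- function(intervals, model = c("cultivar", "null"),
                                quad_order = 15, adapt = TRUE, n_starts = 5,
                                fix_sigma_colony = NULL,
                                fix_sigma_assay = NULL,
                                se = TRUE, start = NULL) {
  model <- match.arg(model)
  m <- interval_matrices(intervals)
  x <- cultivar_indicator(m$info$cultivar)
  if (model == "cultivar" && length(unique(x)) < 2)
    stop("cultivar model needs colonies from both cultivars")
  colony <- m$info$colony_id
  free <- c(log_shape = TRUE, log_rate0 = TRUE,
            beta = model == "cultivar",
            sigma_colony = is.null(fix_sigma_colony),
            sigma_assay = is.null(fix_sigma_assay))
  full0 <- c(log_shape = 0, log_rate0 = 0, beta = 0,
             sigma_colony = fix_sigma_colony %||% 0,
             sigma_assay = fix_sigma_assay %||% 0)
  negll <- function(theta_free) {
    th <- full0; th[names(free)[free]] <- theta_free
    ll_fn <- make_weibull_assay_ll(m, th[["log_rate0"]] + th[["beta"]] * x,
                                   th[["log_shape"]])
    # optim's finite-difference gradient can probe just below the bound
    val <- nested_marginal_loglik(ll_fn, colony,
                                  max(th[["sigma_colony"]], 0),
                                  max(th[["sigma_assay"]], 0),
                                  quad_order, adapt)
    if (!is.finite(val)) 1e10 else -val
  }
  init <- weibull_start(m)
  th0 <- c(init["log_shape"], init["log_rate0"], beta = 0,
           sigma_colony = if (is.null(fix_sigma_colony)) 0.1 else NA,
           sigma_assay = if (is.null(fix_sigma_assay)) 0.1 else NA)
  names(th0) <- names(free)
  starts <- list(th0[free])
  if (n_starts > 1) {
    jit <- with_substream(substream_seed(20130913L, "wf-multistart"),
      lapply(seq_len(n_starts - 1), function(i)
        starts[[1]] + rnorm(length(starts[[1]]), 0, 0.4)))
    jit <- lapply(jit, function(s)
      pmax(s, ifelse(grepl("sigma", names(s)), 0, -Inf)))
    starts <- c(starts, jit)
  }
  lower <- ifelse(grepl("sigma", names(th0[free])), 0, -Inf)
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      optim(s0, negll, method = "L-BFGS-B", lower = lower,
            control = list(factr = 4.5e7, maxit = 300)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimizer starts failed")
  th <- full0; th[names(free)[free]] <- best$par
  boundary <- c(sigma_colony = free[["sigma_colony"]] &&
                  th[["sigma_colony"]] < 1e-4,
                sigma_assay = free[["sigma_assay"]] &&
                  th[["sigma_assay"]] < 1e-4)
  V <- NULL
  if (se) {
    keep <- free
    if (boundary[["sigma_colony"]]) keep[["sigma_colony"]] <- FALSE
    if (boundary[["sigma_assay"]]) keep[["sigma_assay"]] <- FALSE
    V <- fd_vcov(function(tf) {
      t2 <- th; t2[names(keep)[keep]] <- tf
      loglik_at(t2, m, x, colony, quad_order, adapt)
    }, th[names(keep)[keep]])
  }
  ll_fn <- make_weibull_assay_ll(m, th[["log_rate0"]] + th[["beta"]] * x,
                                 th[["log_shape"]])
  pe <- predict_random_effects(ll_fn, colony, th[["sigma_colony"]],
                               th[["sigma_assay"]], quad_order, adapt)
  names(pe$assay) <- m$info$assay_id
  structure(list(
    params = c(shape = unname(exp(th[["log_shape"]])),
               rate0 = unname(exp(th[["log_rate0"]])),
               beta = unname(th[["beta"]]),
               sigma_colony = unname(th[["sigma_colony"]]),
               sigma_assay = unname(th[["sigma_assay"]])),
    theta = th, free = free,
    loglik = -best$value,
    converged = best$convergence == 0,
    boundary = boundary,
    vcov = V$vcov, se = V$se,
    predicted_effects = pe,
    n_obs = c(assays = nrow(m$counts), matured = sum(m$counts),
              censored = sum(m$cens)),
    model = model, quad_order = quad_order, adapt = adapt,
    study_length = max(m$breaks)),
    class = "wf_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

loglik_at <- function(th, m, x, colony, quad_order, adapt) {
  ll_fn <- make_weibull_assay_ll(m, th[["log_rate0"]] + th[["beta"]] * x,
                                 th[["log_shape"]])
  val <- nested_marginal_loglik(ll_fn, colony, max(th[["sigma_colony"]], 0),
                                max(th[["sigma_assay"]], 0), quad_order, adapt)
  if (!is.finite(val)) -1e10 else val
}

# observed-information covariance by central finite differences of a
# log-likelihood function of the free parameter vector
fd_vcov <- function(loglik_fn, theta) {
  p <- length(theta)
  if (!p) return(list(vcov = matrix(0, 0, 0), se = numeric(0)))
  h <- pmax(abs(theta), 0.1) * 1e-4
  H <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
  f0 <- loglik_fn(theta)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (loglik_fn(theta + ei) - 2 * f0 +
                    loglik_fn(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (loglik_fn(theta + ei + ej) - loglik_fn(theta + ei - ej) -
           loglik_fn(theta - ei + ej) + loglik_fn(theta - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  V <- tryCatch(solve(-H), error = function(e) {
    ev <- eigen(-H, symmetric = TRUE)
    val <- pmax(ev$values, 1e-10)
    ev$vectors %*% diag(1 / val, length(val)) %*% t(ev$vectors)
  })
  dimnames(V) <- dimnames(H)
  list(vcov = V, se = sqrt(pmax(diag(V), 0)))
}

#' Fitted-model bands under random-effect quantiles
#'
#' Survival and density curves of the fitted Weibull model with the log rate
#' shifted by lower and upper quantiles of the combined random-effect
#' distribution `Normal(0, sigma_colony^2 + sigma_assay^2)` — the "extreme
#' models" an assay population at those quantiles would follow. With both
#' variance components at zero the bands coincide with the central curve.
#'
#' @param fit a [fit_weibull_frailty()] result.
#' @param q_low,q_high quantiles of the combined random-effect distribution.
#' @param times evaluation grid in days.
#' @return A data frame with columns `cultivar`, `time`, `band`
#'   (`"lower"`/`"central"`/`"upper"`), `survival`, `density`.
#' @export
random_effect_band <- function(fit, q_low = 0.05, q_high = 0.95,
                               times = seq(0, 12, by = 0.1)) {
  if (!inherits(fit, "wf_fit")) stop("fit must be a wf_fit object")
  p <- fit$params
  sig <- sqrt(p[["sigma_colony"]]^2 + p[["sigma_assay"]]^2)
  shifts <- c(lower = qnorm(q_low) * sig, central = 0,
              upper = qnorm(q_high) * sig)
  cultivars <- if (fit$model == "cultivar") .cultivar_levels else "pooled"
  rows <- lapply(cultivars, function(cu) {
    lam0 <- p[["rate0"]] * exp(p[["beta"]] *
      (if (cu == "pooled") 0 else cultivar_indicator(cu)))
    do.call(rbind, lapply(names(shifts), function(b) {
      lam <- lam0 * exp(shifts[[b]])
      data.frame(cultivar = cu, time = times, band = b,
                 survival = weibull_survival(times, p[["shape"]], lam),
                 density = stats::dweibull(times, shape = p[["shape"]],
                                           scale = 1 / lam),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.wf_fit <- function(x, ...) {
  cat("Mixed-effects interval-censored Weibull fit (", x$model,
      " model)\n", sep = "")
  cat(sprintf("  shape = %.4f, rate0 = %.4f/day, beta = %.4f\n",
              x$params[["shape"]], x$params[["rate0"]], x$params[["beta"]]))
  cat(sprintf("  sigma_colony = %.4f%s, sigma_assay = %.4f%s\n",
              x$params[["sigma_colony"]],
              if (x$boundary[["sigma_colony"]]) " (boundary)" else "",
              x$params[["sigma_assay"]],
              if (x$boundary[["sigma_assay"]]) " (boundary)" else ""))
  cat(sprintf("  log-likelihood = %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
logLik.wf_fit <- function(object, ...) {
  structure(object$loglik, df = sum(object$free), class = "logLik")
}

#' @export
coef.wf_fit <- function(object, ...) object$params

#' @export
vcov.wf_fit <- function(object, ...) object$vcov
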