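# Nested Gauss-Hermite marginal likelihood over colony (outer) and assay
# (inner) Normal random effects on a shared linear predictor.
#
# The model likelihood factorises over colonies i:
#   L_i = Int phi(u; sigma_c) Prod_{j in i} [ Int phi(v; sigma_a)
#           exp(l_ij(u + v)) dv ] du
# where l_ij(delta) is the conditional per-assay log-likelihood at linear
# predictor offset delta. The inner (assay) integrals are evaluated with
# mode-adaptive Gauss-Hermite quadrature (vectorised Newton recentring);
# the outer (colony) integral uses prior-scaled Gauss-Hermite nodes, which
# is accurate here because the inner integrals are smooth in u and the
# colony-level variance in this design is small or zero. sigma = 0 levels
# are handled exactly as degenerate (point-mass) integrals.

.gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(order) {
  stopifnot(order >= 1)
  key <- as.character(order)
  if (is.null(.gh_cache[[key]])) {
    if (order == 1) {
      .gh_cache[[key]] <- list(x = 0, logw = 0.5 * log(pi))
    } else {
      g <- pracma::gaussHermite(order)
      .gh_cache[[key]] <- list(x = g$x, logw = log(g$w))
    }
  }
  .gh_cache[[key]]
}

# rowwise log-sum-exp of a matrix
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx0 <- ifelse(is.finite(mx), mx, 0)
  mx0 + log(rowSums(exp(m - mx0))) + ifelse(is.finite(mx), 0, mx - mx0)
}

# log Int phi(v; sigma) exp(ll(u + v)) dv for every cell of the offset
# matrix U (n_assay x n_outer); assay_ll maps an offset matrix to the matrix
# of per-assay conditional log-likelihoods.
inner_log_integral <- function(assay_ll, U, sigma, order, adapt) {
  n <- nrow(U); M <- ncol(U)
  if (sigma == 0) return(assay_ll(U))
  gh <- gh_nodes(order)
  Q <- length(gh$x)
  if (!adapt) {
    off <- U[, rep(seq_len(M), Q), drop = FALSE] +
      matrix(sqrt(2) * sigma * rep(gh$x, each = M), n, M * Q, byrow = TRUE)
    ll <- assay_ll(off)
    lw <- matrix(rep(gh$logw, each = n * M), n * M, Q)
    return(matrix(row_logsumexp(matrix(ll, n * M, Q) + lw) - 0.5 * log(pi),
                  n, M))
  }
  # Newton recentring on h(v) = ll(u + v) - v^2 / (2 sigma^2), vectorised
  # over all (assay, outer-node) cells
  V <- matrix(0, n, M)
  eps <- 1e-3 * max(sigma, 0.1)
  d2 <- matrix(-1 / sigma^2, n, M)
  for (it in 1:3) {
    tri <- assay_ll(cbind(U + V - eps, U + V, U + V + eps))
    fm <- tri[, seq_len(M), drop = FALSE] - (V - eps)^2 / (2 * sigma^2)
    f0 <- tri[, M + seq_len(M), drop = FALSE] - V^2 / (2 * sigma^2)
    fp <- tri[, 2 * M + seq_len(M), drop = FALSE] - (V + eps)^2 / (2 * sigma^2)
    d1 <- (fp - fm) / (2 * eps)
    d2 <- (fp - 2 * f0 + fm) / eps^2
    d2[!is.finite(d2) | d2 > -1e-8] <- -1 / sigma^2
    step <- d1 / d2
    step[!is.finite(step)] <- 0
    V <- V - pmax(pmin(step, 5 * sigma), -5 * sigma)
    V <- pmax(pmin(V, 8 * sigma), -8 * sigma)
  }
  s <- 1 / sqrt(-d2)
  nodes <- matrix(0, n, M * Q)
  for (q in seq_len(Q))
    nodes[, (q - 1) * M + seq_len(M)] <- V + sqrt(2) * s * gh$x[q]
  ll <- assay_ll(U[, rep(seq_len(M), Q), drop = FALSE] + nodes)
  h <- ll + dnorm(nodes, 0, sigma, log = TRUE)
  terms <- matrix(h, n * M, Q) +
    matrix(rep(gh$logw + gh$x^2, each = n * M), n * M, Q)
  matrix(row_logsumexp(terms) + 0.5 * log(2) + log(as.vector(s)), n, M)
}

# total marginal log-likelihood; colony is an integer/factor index per assay
nested_marginal_loglik <- function(assay_ll, colony, sigma_c, sigma_a,
                                   order = 15, adapt = TRUE) {
  colony <- as.integer(factor(colony))
  n <- length(colony)
  if (sigma_c == 0) {
    U <- matrix(0, n, 1)
    logI <- inner_log_integral(assay_ll, U, sigma_a, order, adapt)
    return(sum(logI))
  }
  gh <- gh_nodes(order)
  Q <- length(gh$x)
  u_nodes <- sqrt(2) * sigma_c * gh$x
  U <- matrix(u_nodes, n, Q, byrow = TRUE)
  logI <- inner_log_integral(assay_ll, U, sigma_a, order, adapt)
  H <- rowsum(logI, colony)                      # G x Q
  lw <- matrix(gh$logw, nrow(H), Q, byrow = TRUE)
  sum(row_logsumexp(H + lw) - 0.5 * log(pi))
}

# posterior modes of the random effects given parameter values
predict_random_effects <- function(assay_ll, colony, sigma_c, sigma_a,
                                   order = 15, adapt = TRUE) {
  colony_f <- factor(colony)
  n <- length(colony_f)
  u_hat <- setNames(numeric(nlevels(colony_f)), levels(colony_f))
  if (sigma_c > 0) {
    for (g in seq_len(nlevels(colony_f))) {
      idx <- which(as.integer(colony_f) == g)
      obj <- function(u) {
        U <- matrix(0, n, 1); U[idx, 1] <- u
        sum(inner_log_integral(assay_ll, U, sigma_a, order, adapt)[idx, 1]) +
          dnorm(u, 0, sigma_c, log = TRUE)
      }
      u_hat[g] <- optimize(obj, c(-6, 6) * sigma_c, maximum = TRUE)$maximum
    }
  }
  v_hat <- numeric(n)
  if (sigma_a > 0) {
    u_per_assay <- u_hat[as.integer(colony_f)]
    for (j in seq_len(n)) {
      obj <- function(v) {
        O <- matrix(0, n, 1); O[j, 1] <- u_per_assay[j] + v
        assay_ll(O)[j, 1] + dnorm(v, 0, sigma_a, log = TRUE)
      }
      v_hat[j] <- optimize(obj, c(-6, 6) * sigma_a, maximum = TRUE)$maximum
    }
  }
  list(colony = u_hat, assay = v_hat)
}
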