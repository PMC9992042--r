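# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own computational paths.

# Brute-force probabilistic index: cross-arm pair enumeration with ties = 1/2
pi_bruteforce <- function(r0, r1) {
  tot <- 0
  for (a in r0) for (b in r1) tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(r0) * length(r1))
}

# Toxicity index by direct evaluation of the sorted-product formula,
# written independently (explicit loop, no cumprod)
ti_bruteforce <- function(g) {
  g <- sort(g, decreasing = TRUE)
  total <- 0
  disc <- 1
  for (i in seq_along(g)) {
    total <- total + g[i] * disc
    disc <- disc / (1 + g[i])
  }
  total
}

# P(Z1 <= a, Z2 <= b) for standard bivariate normal with correlation rho,
# by 1-D quadrature over the conditional normal CDF
bvn_cdf <- function(a, b, rho) {
  if (is.infinite(a) && a < 0) return(0)
  if (is.infinite(b) && b < 0) return(0)
  if (is.infinite(a) && is.infinite(b)) return(1)
  if (is.infinite(a)) return(pnorm(b))
  if (is.infinite(b)) return(pnorm(a))
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  }, -Inf, a, rel.tol = 1e-10)$value
}

# Population Spearman correlation of two ordinal variables obtained by
# thresholding an equicorrelated bivariate normal at the quantiles of a
# common marginal p
discretized_spearman <- function(p, rho) {
  K <- length(p)
  cuts <- qnorm(cumsum(p)[-K])
  edges <- c(-Inf, cuts, Inf)
  joint <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) {
    joint[i, j] <- bvn_cdf(edges[i + 1], edges[j + 1], rho) -
      bvn_cdf(edges[i], edges[j + 1], rho) -
      bvn_cdf(edges[i + 1], edges[j], rho) +
      bvn_cdf(edges[i], edges[j], rho)
  }
  # mid-distribution scores
  cumm <- cumsum(p)
  v <- c(0, cumm[-K]) + p / 2
  mu <- sum(v * p)
  s2 <- sum((v - mu)^2 * p)
  ev <- 0
  for (i in 1:K) for (j in 1:K) ev <- ev + (v[i] - mu) * (v[j] - mu) * joint[i, j]
  ev / s2
}

# 25-node adaptive Gauss-Hermite evaluation of the cumulative-logit
# random-intercept marginal log-likelihood, all in plain R
agq_loglik <- function(panel, beta_names, par, include_treatment = TRUE,
                       n_nodes = 25) {
  gq <- statmod::gauss.quad(n_nodes, kind = "hermite")
  base <- panel[panel$time == 1L, ]
  fu <- panel[panel$time >= 2L, ]
  fu <- fu[order(fu$patient_id, fu$time), ]
  baseline <- base$score[match(fu$patient_id, base$patient_id)]
  lev <- sort(unique(fu$score))
  m <- length(lev)
  yk <- match(fu$score, lev)
  times <- sort(unique(fu$time))
  theta <- cumsum(c(par[1], exp(par[1 + seq_len(m - 2)])))
  p_fix <- length(beta_names)
  beta <- par[(m - 1) + seq_len(p_fix)]
  names(beta) <- beta_names
  sigma <- exp(par[length(par)])
  eta <- numeric(nrow(fu))
  if (include_treatment) eta <- eta + beta["trt"] * fu$arm
  for (tt in times[-1]) {
    nm <- paste0("time", tt)
    if (nm %in% beta_names) eta <- eta + beta[nm] * (fu$time == tt)
  }
  eta <- eta + beta["baseline"] * baseline
  cell_logp <- function(k, x) {
    hi <- if (k == m) 1 else plogis(theta[k] - x)
    lo <- if (k == 1) 0 else plogis(theta[k - 1] - x)
    log(pmax(hi - lo, 1e-300))
  }
  joint_log <- function(rows, b) {
    sum(vapply(rows, function(r) cell_logp(yk[r], eta[r] + b), numeric(1))) +
      dnorm(b, 0, sigma, log = TRUE)
  }
  total <- 0
  for (pid in unique(fu$patient_id)) {
    rows <- which(fu$patient_id == pid)
    mode <- stats::optimize(function(b) joint_log(rows, b),
                            interval = c(-8 * sigma - 5, 8 * sigma + 5),
                            maximum = TRUE, tol = 1e-10)$maximum
    h <- 1e-4
    d2 <- (joint_log(rows, mode + h) - 2 * joint_log(rows, mode) +
             joint_log(rows, mode - h)) / h^2
    s <- 1 / sqrt(max(-d2, 1e-8))
    z <- mode + sqrt(2) * s * gq$nodes
    lg <- vapply(z, function(b) joint_log(rows, b), numeric(1))
    lw <- log(gq$weights) + gq$nodes^2 + lg + log(sqrt(2) * s)
    mx <- max(lw)
    total <- total + mx + log(sum(exp(lw - mx)))
  }
  total
}

# quadratic-time middle term of the PIM sandwich: explicit double loop over
# pair couples sharing at least one patient index
pim_middle_bruteforce <- function(Z, P, beta) {
  m <- plogis(drop(Z %*% beta))
  U <- Z * (P - m)
  pairs <- attr(Z, "pairs")
  B <- matrix(0, ncol(Z), ncol(Z))
  n_pairs <- nrow(pairs)
  for (a in seq_len(n_pairs)) for (b in seq_len(n_pairs)) {
    if (length(intersect(pairs[a, ], pairs[b, ])) > 0) {
      B <- B + U[a, ] %o% U[b, ]
    }
  }
  B
}

# tiny deterministic null scenario helpers used across test files
null_scenario <- function(rho = 0.5, n_per_arm = 100L,
                          p = c(0.6, 0.2, 0.1, 0.07, 0.03)) {
  scenario(sprintf("test_null_rho%g", rho), "null_equal_all_times",
           list(replicate(3, p, simplify = FALSE),
                replicate(3, p, simplify = FALSE)),
           rho = rho, n_per_arm = n_per_arm)
}
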