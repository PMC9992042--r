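#' Fit a probabilistic index model
#'
#' Semiparametric regression of the probabilistic index
#' `PI = P(S_i < S_j) + 0.5 P(S_i = S_j)` on covariate contrasts via a logit
#' link. All unordered patient pairs `{i, j}` become pseudo-observations with
#' outcome 1, 0.5 or 0 according to the ordering of their responses and
#' antisymmetric design `Z_ij = X_j - X_i`; the logistic estimating equation
#' `sum Z_ij [P_ij - expit(Z_ij' beta)] = 0` is solved by damped
#' Fisher scoring. The variance of `beta` uses a sandwich estimator whose
#' middle term sums cross-products of pair scores sharing a patient index,
#' the dependence structure pseudo-observations inherit from reusing
#' patients across pairs.
#'
#' With a treatment indicator as the only covariate the fitted
#' `expit(beta_trt)` equals the empirical PI (the Mann-Whitney statistic
#' with ties counted 1/2, divided by `n0 * n1`).
#'
#' @param data Data frame with one row per patient.
#' @param response Name of the response column (a per-patient summary score).
#' @param treatment Name of the 0/1 treatment column.
#' @param covariates Optional character vector of additional covariate
#'   columns (e.g. baseline grade).
#' @param tol Convergence tolerance on the per-pair mean score norm.
#' @param max_iter Iteration cap for Fisher scoring.
#' @return An object of class `pim_fit` with elements `beta`, `vcov`,
#'   `pi_treatment`, `ci95`, `p_value`, `n_pairs`, `converged`, `terms`.
#' @export
#' @examples
#' d <- data.frame(y = c(0, 1, 1, 2), trt = c(0, 0, 1, 1))
#' fit <- fit_pim(d, "y", "trt")
#' fit$pi_treatment  # 0.875
fit_pim <- function(data, response, treatment, covariates = NULL,
                    tol = 1e-10, max_iter = 100L) {
  r <- data[[response]]
  trt <- data[[treatment]]
  if (is.null(r) || is.null(trt)) {
    stop("response/treatment column not found in data", call. = FALSE)
  }
  if (length(unique(trt)) != 2L || !all(trt %in% c(0, 1))) {
    stop("treatment must be a 0/1 indicator with both arms present", call. = FALSE)
  }
  if (min(table(trt)) < 2L) stop("need >= 2 patients per arm", call. = FALSE)
  X <- cbind(trt = as.numeric(trt))
  colnames(X) <- treatment
  for (cv in covariates) {
    if (is.null(data[[cv]])) stop(sprintf("covariate '%s' not found", cv), call. = FALSE)
    X <- cbind(X, as.numeric(data[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  n <- nrow(X)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i_idx <- idx[, 1]
  j_idx <- idx[, 2]
  Z <- X[j_idx, , drop = FALSE] - X[i_idx, , drop = FALSE]
  P <- 0.5 * (sign(r[j_idx] - r[i_idx]) + 1)
  # pairs with identical covariate contrasts carry no information about beta
  keep <- rowSums(Z != 0) > 0
  Z <- Z[keep, , drop = FALSE]
  P <- P[keep]
  i_idx <- i_idx[keep]
  j_idx <- j_idx[keep]
  if (qr(Z)$rank < ncol(Z)) stop("singular pair design", call. = FALSE)
  separated <- mean(P) <= 0 || mean(P) >= 1  # PI driven to 0 or 1

  p <- ncol(Z)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    m <- plogis(eta)
    resid <- P - m
    score <- drop(crossprod(Z, resid))
    if (max(abs(score)) / length(P) < tol) {
      converged <- TRUE
      break
    }
    w <- m * (1 - m)
    A <- crossprod(Z, Z * w)
    step <- tryCatch(solve(A, score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # damped update: halve until the score norm does not blow up
    lambda <- 1
    f0 <- sum(score^2)
    repeat {
      cand <- beta + lambda * step
      s_new <- drop(crossprod(Z, P - plogis(drop(Z %*% cand))))
      if (sum(s_new^2) <= f0 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    if (any(abs(beta) > 30)) break  # separation: PI driven to 0 or 1
  }
  if (separated || any(abs(beta) > 30) || !all(is.finite(beta))) converged <- FALSE

  m <- plogis(drop(Z %*% beta))
  w <- m * (1 - m)
  A <- crossprod(Z, Z * w)
  U <- Z * (P - m)
  Ti <- matrix(0, n, p)
  si <- rowsum(U, i_idx)
  Ti[as.integer(rownames(si)), ] <- si
  sj <- rowsum(U, j_idx)
  Ti[as.integer(rownames(sj)), ] <- Ti[as.integer(rownames(sj)), , drop = FALSE] + sj
  # middle term: sum over pair couples sharing a patient, equal to
  # sum_i T_i T_i' minus one copy of the diagonal pair self-products
  B <- crossprod(Ti) - crossprod(U)
  Ainv <- tryCatch(solve(A), error = function(e) matrix(NA_real_, p, p))
  vcov <- Ainv %*% B %*% Ainv
  dimnames(vcov) <- list(colnames(Z), colnames(Z))
  names(beta) <- colnames(Z)

  se_trt <- sqrt(vcov[1, 1])
  z <- if (se_trt > 0) beta[1] / se_trt else NA_real_
  pval <- if (is.finite(z)) 2 * pnorm(-abs(z)) else NA_real_
  ci_logit <- beta[1] + c(-1, 1) * 1.959963984540054 * se_trt
  structure(
    list(
      beta = beta,
      vcov = vcov,
      pi_treatment = unname(plogis(beta[1])),
      ci95 = unname(plogis(ci_logit)),
      p_value = unname(pval),
      n_pairs = length(P),
      converged = converged,
      terms = colnames(Z),
      n = n
    ),
    class = "pim_fit"
  )
}

#' Wald test for a PIM coefficient
#'
#' Two-sided normal-theory test of a single coefficient on the logit-PI
#' scale; the confidence interval is formed on the logit scale and
#' back-transformed through the expit so its endpoints stay inside (0, 1).
#'
#' @param fit A `pim_fit`.
#' @param coefficient Coefficient name (default: the treatment term).
#' @param level Confidence level.
#' @return A list with `statistic`, `p_value` and `ci95` (on the PI scale).
#' @export
wald_test <- function(fit, coefficient = fit$terms[1], level = 0.95) {
  k <- match(coefficient, fit$terms)
  if (is.na(k)) stop(sprintf("no coefficient '%s' in fit", coefficient), call. = FALSE)
  se <- sqrt(fit$vcov[k, k])
  if (!is.finite(se) || se <= 0) {
    stop("degenerate inference: coefficient standard error is zero", call. = FALSE)
  }
  z <- fit$beta[k] / se
  q <- qnorm(1 - (1 - level) / 2)
  list(
    statistic = unname(z),
    p_value = unname(2 * pnorm(-abs(z))),
    ci95 = unname(plogis(fit$beta[k] + c(-1, 1) * q * se))
  )
}

#' @export
print.pim_fit <- function(x, ...) {
  cat("<probabilistic index model fit>\n")
  cat(sprintf("  terms: %s | pairs: %d | converged: %s\n",
              paste(x$terms, collapse = ", "), x$n_pairs, x$converged))
  cat(sprintf("  PI(treatment) = %.4f  95%% CI [%.4f, %.4f]  p = %.4g\n",
              x$pi_treatment, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Tidy a PIM fit
#'
#' @param x A `pim_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` (logit
#'   scale), `std.error`, `statistic`, `p.value`.
#' @export
tidy.pim_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = unname(2 * pnorm(-abs(x$beta / se)))
  )
}

#' One-row summary of a PIM fit
#'
#' @param x A `pim_fit`.
#' @param ... Unused.
#' @return A tibble with `pi`, `ci_low`, `ci_high`, `p_value`, `n_pairs`,
#'   `converged`.
#' @export
glance.pim_fit <- function(x, ...) {
  tibble::tibble(
    pi = x$pi_treatment,
    ci_low = x$ci95[1],
    ci_high = x$ci95[2],
    p_value = x$p_value,
    n_pairs = x$n_pairs,
    converged = x$converged
  )
}
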