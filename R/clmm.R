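# Design construction shared by fit_clmm() and the parametric bootstrap:
# follow-up scores (time >= 2) are the response; fixed effects are the
# treatment indicator (optional), indicator coding of each follow-up time
# beyond the first (time 2 = reference), and the numeric baseline grade.
clmm_design <- function(panel, include_treatment = TRUE) {
  if (!all(c("patient_id", "arm", "time", "score") %in% names(panel))) {
    stop("panel must have columns patient_id, arm, time, score", call. = FALSE)
  }
  base <- panel[panel$time == 1L, ]
  if (nrow(base) == 0L) stop("panel has no baseline (time 1) rows", call. = FALSE)
  fu <- panel[panel$time >= 2L, ]
  fu <- fu[order(fu$patient_id, fu$time), ]
  baseline <- base$score[match(fu$patient_id, base$patient_id)]
  if (any(is.na(baseline))) stop("every patient needs a baseline observation", call. = FALSE)
  times <- sort(unique(fu$time))
  Xcols <- list()
  if (include_treatment) Xcols$trt <- as.numeric(fu$arm)
  for (tt in times[-1]) Xcols[[paste0("time", tt)]] <- as.numeric(fu$time == tt)
  Xcols$baseline <- as.numeric(baseline)
  X <- do.call(cbind, Xcols)
  pid <- fu$patient_id
  runs <- rle(as.character(pid))$lengths
  pat_start <- as.integer(c(0L, cumsum(runs)))
  list(
    score = fu$score,
    X = X,
    pat_start = pat_start,
    patient_id = unique(pid),
    fu = fu
  )
}

fit_clmm_core <- function(score, X, pat_start, start = NULL, se = FALSE,
                          xcode = NULL) {
  lev <- sort(unique(score))
  m <- length(lev)
  if (m < 2L) stop("fewer than 2 observed response categories", call. = FALSE)
  y <- match(score, lev) - 1L
  p <- ncol(X)
  np <- (m - 1L) + p + 1L
  if (is.null(start) || length(start) != np) {
    cum <- cumsum(tabulate(y + 1L, nbins = m)) / length(y)
    q <- qlogis(pmin(pmax(cum[-m], 1e-6), 1 - 1e-6))
    d <- pmax(diff(q), 1e-3)
    start <- c(q[1], log(d), rep(0, p), 0)
  }
  lower <- c(-30, rep(-20, m - 2L), rep(-30, p), log(1e-6))
  upper <- c(30, rep(10, m - 2L), rep(30, p), log(50))

  # collapse patients sharing an identical (response, covariate) block into
  # one weighted pseudo-patient: their marginal likelihood contributions are
  # identical, so the collapsed likelihood is exact
  n_patients <- length(pat_start) - 1L
  yf <- y; Xf <- X; psf <- pat_start; w <- rep(1, n_patients)
  nt <- diff(pat_start)
  if (n_patients > 8L && length(unique(nt)) == 1L) {
    ntc <- nt[1]
    if (!is.null(xcode) && m^ntc * (max(xcode) + 1) < 2^52) {
      # fast path: covariate patterns precomputed by the caller, response
      # pattern encoded base-m
      ycode <- numeric(n_patients)
      for (t in seq_len(ntc)) {
        ycode <- ycode * m + y[seq(t, length(y), by = ntc)]
      }
      key <- ycode * (max(xcode) + 1) + xcode
    } else {
      cols <- c(
        lapply(seq_len(ntc), function(t) y[seq(t, length(y), by = ntc)]),
        unlist(lapply(seq_len(p), function(j) {
          lapply(seq_len(ntc), function(t) X[seq(t, nrow(X), by = ntc), j])
        }), recursive = FALSE)
      )
      key <- do.call(paste, c(cols, list(sep = ",")))
    }
    first <- !duplicated(key)
    if (sum(first) < n_patients) {
      gid <- match(key, key[first])
      w <- as.numeric(tabulate(gid, nbins = sum(first)))
      keep <- as.vector(vapply(which(first), function(r) (r - 1L) * ntc + seq_len(ntc),
                               integer(ntc)))
      yf <- y[keep]
      Xf <- X[keep, , drop = FALSE]
      psf <- as.integer(seq.int(0L, sum(first) * ntc, by = ntc))
    }
  }

  bhat <- numeric(length(psf) - 1L)  # warm-started conditional modes
  # primary path: built-in quasi-Newton driver (no R callbacks); fall back
  # to nlminb with the same objective/gradient if it stalls
  bf <- clmm_bfgs_cpp(start, yf, Xf, psf, m, w, 300L, 1e-7)
  opt <- NULL
  if (isTRUE(bf$converged) && all(is.finite(bf$par)) &&
      all(bf$par >= lower - 1) && all(bf$par <= upper + 1)) {
    par <- pmin(pmax(bf$par, lower), upper)
    nll <- bf$value
    converged <- TRUE
  } else {
    cache <- new.env(parent = emptyenv())
    evaluate <- function(par) {
      if (is.null(cache$par) || !identical(cache$par, par)) {
        cache$res <- clmm_obj_grad_cpp(par, yf, Xf, psf, m, bhat, w, TRUE)
        cache$par <- par
      }
      cache$res
    }
    obj <- function(par) evaluate(par)$value
    gr <- function(par) evaluate(par)$gradient
    opt <- stats::nlminb(start, obj, gradient = gr, lower = lower, upper = upper,
                         control = list(iter.max = 300L, eval.max = 600L,
                                        rel.tol = 1e-9))
    par <- opt$par
    nll <- opt$objective
    gfin <- gr(par)
    # accept the optimum if the optimizer reports convergence or the scaled
    # gradient is small (bound-active coordinates excluded)
    interior <- par > lower + 1e-8 & par < upper - 1e-8
    gnorm <- max(abs(gfin[interior]), 0)
    converged <- is.finite(nll) &&
      (opt$convergence == 0L || gnorm < 1e-3 * (1 + abs(nll)))
  }
  theta <- cumsum(c(par[1], exp(par[seq_len(m - 2L) + 1L])))
  beta <- par[(m - 1L) + seq_len(p)]
  names(beta) <- colnames(X)
  sigma_b <- exp(par[np])

  vcov_par <- NULL
  if (se) {
    H <- matrix(0, np, np)
    for (k in seq_len(np)) {
      h <- 1e-5 * (1 + abs(par[k]))
      pk <- par; pk[k] <- par[k] + h
      gu <- clmm_obj_grad_cpp(pk, yf, Xf, psf, m, bhat, w, TRUE)$gradient
      pk[k] <- par[k] - h
      gl <- clmm_obj_grad_cpp(pk, yf, Xf, psf, m, bhat, w, TRUE)$gradient
      H[, k] <- (gu - gl) / (2 * h)
    }
    H <- (H + t(H)) / 2
    vcov_par <- tryCatch(solve(H), error = function(e) NULL)
  }
  list(par = par, theta = theta, beta = beta, sigma_b = sigma_b,
       loglik = -nll, converged = converged, m = m, lev = lev,
       vcov_par = vcov_par, n_obs = length(y), opt = opt)
}

#' Fit a cumulative logit mixed model
#'
#' Proportional-odds model for the follow-up scores with a random patient
#' intercept: `logit P(Y_it <= k | b_i) = theta_k - (eta_it + b_i)` with
#' `b_i ~ N(0, sigma_b^2)` and linear predictor containing the treatment
#' indicator (optional), indicator coding of follow-up time (time 2 as
#' reference) and the numeric baseline grade. The marginal likelihood is
#' maximised with a Laplace approximation to each patient's random-effect
#' integral; `sigma_b` is optimised on the log scale and cutpoint ordering is
#' enforced by optimising log-increments.
#'
#' @param panel Long-format panel tibble; time 1 rows supply the baseline
#'   covariate, times >= 2 are modelled.
#' @param include_treatment Include the treatment term (`FALSE` gives the
#'   null model for likelihood-ratio testing).
#' @param se Compute the parameter covariance (numerical Hessian); skipped
#'   in tight simulation loops.
#' @param start Optional warm-start parameter vector (as returned in
#'   `$par`).
#' @return An object of class `clmm_fit`: `cutpoints`, `beta`, `sigma_b`,
#'   `loglik`, `converged`, `or_treatment` (with 95% Wald CI when `se` and a
#'   treatment term are present), `n_obs`, `n_patients`.
#' @export
fit_clmm <- function(panel, include_treatment = TRUE, se = FALSE, start = NULL) {
  des <- clmm_design(panel, include_treatment)
  core <- fit_clmm_core(des$score, des$X, des$pat_start, start = start, se = se)
  or_treatment <- NULL
  if (include_treatment) {
    b <- unname(core$beta["trt"])
    or_treatment <- list(or = exp(b), ci95 = c(NA_real_, NA_real_))
    if (!is.null(core$vcov_par)) {
      k <- core$m - 1L + 1L  # trt is the first fixed-effect column
      se_b <- sqrt(core$vcov_par[k, k])
      or_treatment$se_log <- se_b
      or_treatment$ci95 <- exp(b + c(-1, 1) * 1.959963984540054 * se_b)
    }
  }
  structure(
    list(
      cutpoints = core$theta,
      beta = core$beta,
      sigma_b = core$sigma_b,
      loglik = core$loglik,
      converged = core$converged,
      or_treatment = or_treatment,
      levels = core$lev,
      m = core$m,
      par = core$par,
      vcov_par = core$vcov_par,
      n_obs = core$n_obs,
      n_patients = length(des$patient_id),
      include_treatment = include_treatment,
      design = des
    ),
    class = "clmm_fit"
  )
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat("<cumulative logit mixed model fit (Laplace)>\n")
  cat(sprintf("  obs: %d  patients: %d  categories: %d  converged: %s\n",
              x$n_obs, x$n_patients, x$m, x$converged))
  cat(sprintf("  logLik: %.4f  sigma_b: %.4f\n", x$loglik, x$sigma_b))
  cat("  cutpoints:", paste(formatC(x$cutpoints, format = "f", digits = 3),
                            collapse = " "), "\n")
  cat("  beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta), collapse = "  "), "\n")
  if (!is.null(x$or_treatment) && is.finite(x$or_treatment$ci95[1])) {
    cat(sprintf("  OR(treatment) = %.3f  95%% CI [%.3f, %.3f]\n",
                x$or_treatment$or, x$or_treatment$ci95[1], x$or_treatment$ci95[2]))
  }
  invisible(x)
}

#' Tidy a CLMM fit
#'
#' @param x A `clmm_fit`.
#' @param ... Unused.
#' @return A tibble of model terms: cutpoints, fixed effects and the
#'   random-intercept SD, with standard errors for the fixed effects when the
#'   fit carries a Hessian.
#' @export
tidy.clmm_fit <- function(x, ...) {
  terms <- c(paste0("theta_", seq_along(x$cutpoints)), names(x$beta), "sigma_b")
  est <- c(x$cutpoints, unname(x$beta), x$sigma_b)
  se <- rep(NA_real_, length(est))
  if (!is.null(x$vcov_par)) {
    idx <- x$m - 1L + seq_along(x$beta)
    se[x$m - 1L + seq_along(x$beta)] <- sqrt(diag(x$vcov_par)[idx])
  }
  tibble::tibble(term = terms, estimate = est, std.error = se)
}

#' One-row summary of a CLMM fit
#'
#' @param x A `clmm_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `sigma_b`, `or_treatment`, `converged`,
#'   `n_obs`, `n_patients`.
#' @export
glance.clmm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    sigma_b = x$sigma_b,
    or_treatment = if (is.null(x$or_treatment)) NA_real_ else x$or_treatment$or,
    converged = x$converged,
    n_obs = x$n_obs,
    n_patients = x$n_patients
  )
}

#' Chi-square likelihood-ratio test between nested CLMM fits
#'
#' @param null_fit,alt_fit Converged `clmm_fit` objects on the same data,
#'   with the alternative nesting the null (here: with vs without the
#'   treatment term).
#' @return A list of class `propower_lrt`: `statistic` (clipped at 0), `df`,
#'   `p_value`, `method = "chisq"`.
#' @export
lrt_chisq <- function(null_fit, alt_fit) {
  if (!inherits(null_fit, "clmm_fit") || !inherits(alt_fit, "clmm_fit")) {
    stop("both arguments must be clmm_fit objects", call. = FALSE)
  }
  if (null_fit$n_obs != alt_fit$n_obs || null_fit$m != alt_fit$m) {
    stop("fits are not on the same data", call. = FALSE)
  }
  df <- length(alt_fit$beta) - length(null_fit$beta)
  if (df < 0 || !all(names(null_fit$beta) %in% names(alt_fit$beta))) {
    stop("models are not nested (null terms must be a subset of alternative terms)",
         call. = FALSE)
  }
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < -1e-6) {
    warning("alternative log-likelihood below null beyond tolerance; clipping LR to 0")
  }
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p, method = "chisq"),
            class = "propower_lrt")
}

#' @export
print.propower_lrt <- function(x, ...) {
  cat(sprintf("<LRT (%s)> statistic = %.4f", x$method, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  if (!is.null(x$n_boot)) cat(sprintf(", B = %d", x$n_boot))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

# per-patient covariate-block pattern codes, precomputed once per design so
# the bootstrap's repeated pattern collapses reduce to integer arithmetic
design_xcode <- function(X, pat_start) {
  nt <- diff(pat_start)
  if (length(unique(nt)) != 1L) return(NULL)
  ntc <- nt[1]
  cols <- unlist(lapply(seq_len(ncol(X)), function(j) {
    lapply(seq_len(ntc), function(t) X[seq(t, nrow(X), by = ntc), j])
  }), recursive = FALSE)
  key <- do.call(paste, c(cols, list(sep = ",")))
  match(key, unique(key)) - 1L
}

# simulate follow-up responses from a fitted null model at freshly drawn
# random intercepts; returns integer scores on the original score scale
simulate_from_clmm <- function(core, X, pat_start) {
  n_pat <- length(pat_start) - 1L
  n_obs <- nrow(X)
  b <- rnorm(n_pat, 0, core$sigma_b)
  obs_b <- b[rep(seq_len(n_pat), times = diff(pat_start))]
  eta <- drop(X %*% core$beta) + obs_b
  cum <- plogis(outer(-eta, core$theta, `+`))  # n_obs x (m-1), P(Y <= k)
  u <- runif(n_obs)
  yi <- rowSums(u > cum)
  core$lev[yi + 1L]
}

#' Parametric-bootstrap likelihood-ratio test for the treatment effect
#'
#' Instead of referring the likelihood-ratio statistic to a chi-square
#' distribution, its null distribution is rebuilt by simulation: the null
#' model (no treatment term) is fitted, new random intercepts are drawn from
#' the fitted `N(0, sigma_b^2)` and new follow-up responses are simulated
#' from the fitted null category probabilities given each observation's time
#' and baseline; both models are refitted on every resample. The p-value
#' uses the add-one convention `(1 + #{LR* >= LR_obs}) / (B + 1)`, so it is
#' bounded below by `1/(B+1)`. Resamples whose refits fail to converge are
#' redrawn (fresh responses) up to `max_refit_redraws` times each, keeping B
#' fixed.
#'
#' @param panel Long-format panel tibble (admissible).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed for the resampling stream.
#' @param max_refit_redraws Redraw budget per resample.
#' @return A list of class `propower_lrt`: `statistic`, `p_value`,
#'   `method = "bootstrap"`, `n_boot`, `boot_stats`, `n_redrawn`, plus the
#'   observed `null_fit`/`alt_fit`.
#' @export
lrt_bootstrap <- function(panel, B = 500L, seed = 1L, max_refit_redraws = 10L) {
  stopifnot(B >= 1L)
  des0 <- clmm_design(panel, include_treatment = FALSE)
  des1 <- clmm_design(panel, include_treatment = TRUE)
  xc0 <- design_xcode(des0$X, des0$pat_start)
  xc1 <- design_xcode(des1$X, des1$pat_start)
  fit0 <- fit_clmm_core(des0$score, des0$X, des0$pat_start, xcode = xc0)
  fit1 <- fit_clmm_core(des1$score, des1$X, des1$pat_start, xcode = xc1)
  if (!fit0$converged || !fit1$converged) {
    stop("observed-data CLMM fits did not converge", call. = FALSE)
  }
  lr_obs <- max(0, 2 * (fit1$loglik - fit0$loglik))
  set.seed(as.integer(seed))
  boot_stats <- numeric(B)
  n_redrawn <- 0L
  for (bb in seq_len(B)) {
    ok <- FALSE
    for (attempt in seq_len(max_refit_redraws + 1L)) {
      ystar <- simulate_from_clmm(fit0, des0$X, des0$pat_start)
      if (length(unique(ystar)) < 2L) { n_redrawn <- n_redrawn + 1L; next }
      same_lev <- identical(sort(unique(ystar)), fit0$lev)
      r0 <- tryCatch(
        fit_clmm_core(ystar, des0$X, des0$pat_start,
                      start = if (same_lev) fit0$par else NULL, xcode = xc0),
        error = function(e) NULL)
      r1 <- tryCatch(
        fit_clmm_core(ystar, des1$X, des1$pat_start,
                      start = if (same_lev) fit1$par else NULL, xcode = xc1),
        error = function(e) NULL)
      if (!is.null(r0) && !is.null(r1) && r0$converged && r1$converged) {
        boot_stats[bb] <- max(0, 2 * (r1$loglik - r0$loglik))
        ok <- TRUE
        break
      }
      n_redrawn <- n_redrawn + 1L
    }
    if (!ok) {
      stop(sprintf("bootstrap resample %d: refits failed after %d redraws",
                   bb, max_refit_redraws), call. = FALSE)
    }
  }
  p <- (1 + sum(boot_stats >= lr_obs)) / (B + 1)
  structure(
    list(statistic = lr_obs, df = NULL, p_value = p, method = "bootstrap",
         n_boot = B, boot_stats = boot_stats, n_redrawn = n_redrawn,
         null_loglik = fit0$loglik, alt_loglik = fit1$loglik),
    class = "propower_lrt"
  )
}
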