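# simulate a panel directly from a proportional-odds model with a random
# patient intercept (independent of the copula machinery)
simulate_clmm_panel <- function(n_per_arm, theta, beta_trt, beta_time3,
                                beta_base, sigma_b, seed,
                                base_probs = c(0.5, 0.25, 0.15, 0.07, 0.03)) {
  set.seed(seed)
  n <- 2L * n_per_arm
  arm <- rep(c(0L, 1L), each = n_per_arm)
  baseline <- sample(0:4, n, replace = TRUE, prob = base_probs)
  b <- rnorm(n, 0, sigma_b)
  draw <- function(eta) {
    cum <- outer(eta, theta, function(e, th) plogis(th - e))
    rowSums(runif(length(eta)) > cum)
  }
  y2 <- draw(beta_trt * arm + beta_base * baseline + b)
  y3 <- draw(beta_trt * arm + beta_time3 + beta_base * baseline + b)
  tibble::tibble(
    patient_id = rep(seq_len(n), each = 3L),
    arm = rep(arm, each = 3L),
    time = rep(1:3, times = n),
    score = as.integer(rbind(baseline, y2, y3))
  )
}

test_that("with no random-effect variance the fit collapses to ordinary
           proportional-odds ML", {
  skip_if_not_installed("MASS")
  panel <- simulate_clmm_panel(300, theta = c(-0.5, 0.5, 1.5, 2.5),
                               beta_trt = 0.6, beta_time3 = 0.3,
                               beta_base = 0.25, sigma_b = 0, seed = 2024)
  fit <- fit_clmm(panel, include_treatment = TRUE)
  expect_true(fit$converged)
  expect_lt(fit$sigma_b, 0.05)
  fu <- panel[panel$time >= 2, ]
  base <- panel[panel$time == 1, ]
  fu$baseline <- base$score[match(fu$patient_id, base$patient_id)]
  fu$time3 <- as.numeric(fu$time == 3)
  po <- MASS::polr(factor(score) ~ arm + time3 + baseline, data = fu,
                   method = "logistic")
  expect_equal(unname(fit$beta["trt"]), unname(po$coefficients["arm"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$beta["time3"]), unname(po$coefficients["time3"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$beta["baseline"]), unname(po$coefficients["baseline"]),
               tolerance = 1e-3)
  expect_equal(unname(fit$cutpoints), unname(po$zeta), tolerance = 2e-3)
})

test_that("Laplace log-likelihood tracks 25-node adaptive quadrature", {
  skip_if_not_installed("statmod")
  for (seed in c(5, 17)) {
    panel <- simulate_clmm_panel(25, theta = c(-1, 0.2, 1.2, 2.3),
                                 beta_trt = 0.5, beta_time3 = 0.2,
                                 beta_base = 0.3, sigma_b = 1, seed = seed)
    fit <- fit_clmm(panel, include_treatment = TRUE)
    ll_agq <- agq_loglik(panel, names(fit$beta), fit$par)
    expect_equal(fit$loglik, ll_agq, tolerance = 0.005 * abs(ll_agq))
  }
})

test_that("nesting: adding the treatment term cannot decrease the log-likelihood", {
  sc <- null_scenario(rho = 0.5)
  for (seed in c(1, 2, 3)) {
    panel <- simulate_admissible(sc, seed)
    f0 <- fit_clmm(panel, include_treatment = FALSE)
    f1 <- fit_clmm(panel, include_treatment = TRUE)
    expect_true(f0$converged && f1$converged)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
    expect_true(all(diff(f1$cutpoints) > 0))
    expect_gte(f1$sigma_b, 0)
  }
})

test_that("chi-square LRT computes, clips and validates correctly", {
  sc <- null_scenario(rho = 0.5)
  panel <- simulate_admissible(sc, 4)
  f0 <- fit_clmm(panel, include_treatment = FALSE)
  f1 <- fit_clmm(panel, include_treatment = TRUE)
  lr <- lrt_chisq(f0, f1)
  expect_equal(lr$df, 1L)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$p_value,
               pchisq(lr$statistic, 1, lower.tail = FALSE), tolerance = 1e-12)
  # identical fits: statistic 0, p 1
  lr0 <- lrt_chisq(f1, f1)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # tiny negative excursions are clipped
  fa <- f1; fa$loglik <- f0$loglik - 1e-8
  fa$beta <- f1$beta
  lrc <- lrt_chisq(f0, fa)
  expect_equal(lrc$statistic, 0)
  expect_equal(lrc$p_value, 1)
  expect_error(lrt_chisq(f1, f0), "nested")
  p2 <- simulate_admissible(sc, 99)
  expect_error(lrt_chisq(fit_clmm(p2, FALSE), f1), NA)  # same shape passes checks
})

test_that("shifting one arm upward drives the treatment odds ratio above one", {
  sc <- null_scenario(rho = 0.5)
  panel <- simulate_admissible(sc, 10)
  shifted <- panel
  idx <- shifted$arm == 1 & shifted$time >= 2
  shifted$score[idx] <- pmin(shifted$score[idx] + 1L, 4L)
  f_null <- fit_clmm(panel, include_treatment = TRUE, se = TRUE)
  f_shift <- fit_clmm(shifted, include_treatment = TRUE, se = TRUE)
  expect_gt(unname(f_shift$beta["trt"]), unname(f_null$beta["trt"]))
  expect_gt(f_shift$or_treatment$or, 1)
  expect_true(f_shift$or_treatment$ci95[1] > 0)
})

test_that("parametric bootstrap p-values are reproducible and bounded below", {
  sc <- null_scenario(rho = 0.5, n_per_arm = 60L)
  panel <- simulate_admissible(sc, 21)
  lb1 <- lrt_bootstrap(panel, B = 30, seed = 5)
  lb2 <- lrt_bootstrap(panel, B = 30, seed = 5)
  expect_identical(lb1$p_value, lb2$p_value)
  expect_identical(lb1$boot_stats, lb2$boot_stats)
  expect_length(lb1$boot_stats, 30L)
  expect_gte(lb1$p_value, 1 / 31)
  expect_lte(lb1$p_value, 1)
  expect_true(all(lb1$boot_stats >= 0))
  lb3 <- lrt_bootstrap(panel, B = 30, seed = 6)
  expect_false(identical(lb1$boot_stats, lb3$boot_stats))
})

test_that("tidy and glance expose the CLMM parameters", {
  sc <- null_scenario(rho = 0.5, n_per_arm = 50L)
  panel <- simulate_admissible(sc, 2)
  fit <- fit_clmm(panel, include_treatment = TRUE, se = TRUE)
  td <- tidy(fit)
  expect_true(all(c("theta_1", "trt", "baseline", "sigma_b") %in% td$term))
  expect_true(all(is.finite(td$estimate)))
  expect_true(is.finite(td$std.error[td$term == "trt"]))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(gl$n_patients, 100L)
})
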