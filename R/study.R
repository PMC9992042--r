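#' Method labels of the eight analysis strategies
#'
#' Six probabilistic-index-model strategies (baseline-adjusted `BA` or
#' baseline-as-covariate `BC`, each with the TI, Avg or Max summary) plus
#' the cumulative logit mixed model tested by chi-square LRT (`CLMM`) and by
#' parametric-bootstrap LRT (`CLMM-Bootstrap`).
#'
#' @return Character vector of the eight labels.
#' @export
all_methods <- function() {
  c("PIM-BA-TI", "PIM-BA-Avg", "PIM-BA-Max",
    "PIM-BC-TI", "PIM-BC-Avg", "PIM-BC-Max",
    "CLMM", "CLMM-Bootstrap")
}

#' Monte-Carlo confidence band for an empirical rejection rate
#'
#' Normal-approximation band `alpha +/- 1.96 sqrt(alpha (1 - alpha) /
#' n_reps)` within which the simulated type I error rate of a well-calibrated
#' test is expected to fall; rates below are conservative, above
#' anti-conservative.
#'
#' @param alpha Nominal level.
#' @param n_reps Number of simulation replicates.
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' mc_ci_band(0.05, 1000)  # c(0.0365, 0.0635)
mc_ci_band <- function(alpha, n_reps) {
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1)
  half <- 1.96 * sqrt(alpha * (1 - alpha) / n_reps)
  c(lower = alpha - half, upper = alpha + half)
}

# Deterministic per-replicate seed: FNV-style hash of the scenario label
# folded with the master seed and replicate index, reduced mod 2^31 - 1 so
# it stays a valid 32-bit seed.
replicate_seed <- function(master_seed, label, replicate) {
  M <- 2147483647
  h <- (as.numeric(master_seed) %% M)
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% M
  h <- (h * 31 + as.numeric(replicate) * 2654435761) %% M
  as.integer(h %% (M - 1000000L)) + 1L
}

run_methods_on_panel <- function(panel, methods, n_boot, boot_seed) {
  out <- list()
  need_sum <- any(grepl("^PIM", methods))
  if (need_sum) {
    measures <- unique(sub("^PIM-B[AC]-", "", grep("^PIM", methods, value = TRUE)))
    strategies <- c(
      if (any(grepl("^PIM-BA", methods))) "baseline_adjusted",
      if (any(grepl("^PIM-BC", methods))) "post_baseline"
    )
    summ <- summarize_panel(panel, measures = measures, strategies = strategies)
  }
  for (mth in methods) {
    if (grepl("^PIM", mth)) {
      meas <- sub("^PIM-B[AC]-", "", mth)
      if (grepl("^PIM-BA", mth)) {
        d <- summ[summ$measure == meas & summ$strategy == "baseline_adjusted", ]
        fit <- tryCatch(fit_pim(d, "value", "arm"), error = function(e) NULL)
      } else {
        d <- summ[summ$measure == meas & summ$strategy == "post_baseline", ]
        fit <- tryCatch(fit_pim(d, "value", "arm", covariates = "baseline"),
                        error = function(e) NULL)
      }
      if (is.null(fit) || !fit$converged || !is.finite(fit$p_value)) return(NULL)
      out[[mth]] <- fit$p_value
    } else if (mth == "CLMM") {
      f0 <- tryCatch(fit_clmm(panel, include_treatment = FALSE), error = function(e) NULL)
      f1 <- tryCatch(fit_clmm(panel, include_treatment = TRUE), error = function(e) NULL)
      if (is.null(f0) || is.null(f1) || !f0$converged || !f1$converged) return(NULL)
      out[[mth]] <- lrt_chisq(f0, f1)$p_value
    } else if (mth == "CLMM-Bootstrap") {
      lb <- tryCatch(lrt_bootstrap(panel, B = n_boot, seed = boot_seed),
                     error = function(e) NULL)
      if (is.null(lb)) return(NULL)
      out[[mth]] <- lb$p_value
    } else {
      stop(sprintf("unknown method label '%s'", mth), call. = FALSE)
    }
  }
  out
}

#' Run one simulation replicate
#'
#' Simulates an admissible panel from the scenario and applies the requested
#' analysis methods. If any fitted model fails to converge the whole panel
#' is redrawn (with a deterministically advanced seed), so results are not
#' contaminated by numerical convergence failures; the number of redraws is
#' reported.
#'
#' @param sc A `propower_scenario`.
#' @param methods Subset of [all_methods()].
#' @param seed Integer seed for this replicate.
#' @param n_boot Bootstrap resamples for `CLMM-Bootstrap`.
#' @param max_redraws Redraw budget (admissibility redraws and model-failure
#'   redraws combined).
#' @return A tibble with columns `method`, `p_value`, `redraws`.
#' @export
run_replicate <- function(sc, methods = all_methods(), seed = 1L,
                          n_boot = 500L, max_redraws = 20L) {
  methods <- match.arg(methods, all_methods(), several.ok = TRUE)
  for (attempt in 0:max_redraws) {
    seed_cur <- (seed + attempt * 1009L) %% 2147483647L
    panel <- tryCatch(simulate_admissible(sc, seed_cur, max_redraws = max_redraws),
                      error = function(e) NULL)
    if (is.null(panel)) next
    res <- run_methods_on_panel(panel, methods, n_boot,
                                boot_seed = (seed_cur + 7L) %% 2147483647L)
    if (!is.null(res)) {
      return(tibble::tibble(
        method = names(res),
        p_value = unname(unlist(res)),
        redraws = attempt + attr(panel, "redraws")
      ))
    }
  }
  stop(sprintf("scenario '%s': replicate failed after %d redraws",
               sc$label, max_redraws), call. = FALSE)
}

#' Estimate rejection rates for one scenario
#'
#' Runs `n_reps` independent replicates (per-replicate seeds derived
#' deterministically from `master_seed` and the scenario label) and returns
#' the proportion of p-values below `alpha` with its binomial standard
#' error. For a null scenario this is the type I error rate; otherwise it is
#' power.
#'
#' @param sc A `propower_scenario`.
#' @param methods Subset of [all_methods()].
#' @param n_reps Number of replicates.
#' @param master_seed Master seed.
#' @param alpha Significance level.
#' @param n_boot Bootstrap resamples for `CLMM-Bootstrap`.
#' @param max_redraws Per-replicate redraw budget; replicates that exhaust it
#'   are excluded from the denominator and counted in `n_failed`.
#' @return A tibble with one row per method: `method`, `rate`, `se`,
#'   `n_used`, `n_failed`.
#' @export
estimate_rejection <- function(sc, methods = all_methods(), n_reps = 1000L,
                               master_seed = 1L, alpha = 0.05,
                               n_boot = 500L, max_redraws = 20L) {
  rows <- run_study(list(sc), methods = methods, n_reps = n_reps,
                    master_seed = master_seed, alpha = alpha,
                    n_boot = n_boot, max_redraws = max_redraws)
  if (nrow(rows) == 0L) {
    stop(sprintf("scenario '%s': every replicate failed; nothing to estimate",
                 sc$label), call. = FALSE)
  }
  rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      rate = mean(.data$p_value < alpha),
      se = sqrt(rate * (1 - rate) / dplyr::n()),
      n_used = dplyr::n(),
      n_failed = n_reps - dplyr::n(),
      .groups = "drop"
    )
}

#' Run a full replicate study over a scenario grid
#'
#' The workhorse behind the type I error / power comparisons: for every
#' scenario and replicate, simulates a panel and records each method's
#' p-value. Per-replicate seeds are hashed from `(master_seed,
#' scenario label, replicate)`, so scenario lists can be extended without
#' disturbing existing replicate streams and results are invariant to
#' execution order.
#'
#' @param scenarios List of `propower_scenario` objects.
#' @param methods Subset of [all_methods()].
#' @param n_reps Replicates per scenario.
#' @param master_seed Master seed.
#' @param alpha Significance level (recorded, used downstream).
#' @param n_boot Bootstrap resamples for `CLMM-Bootstrap`.
#' @param max_redraws Per-replicate redraw budget.
#' @return A tibble of replicate rows: `scenario`, `family`, `rho`,
#'   `is_null`, `method`, `replicate`, `p_value`, `redraws`.
#' @export
run_study <- function(scenarios, methods = all_methods(), n_reps = 1000L,
                      master_seed = 1L, alpha = 0.05, n_boot = 500L,
                      max_redraws = 20L) {
  stopifnot(alpha > 0, alpha < 1, n_reps >= 1)
  out <- vector("list", length(scenarios))
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      seed_r <- replicate_seed(master_seed, sc$label, r)
      row <- tryCatch(
        run_replicate(sc, methods, seed = seed_r, n_boot = n_boot,
                      max_redraws = max_redraws),
        error = function(e) NULL)
      if (!is.null(row)) reps[[r]] <- dplyr::mutate(row, replicate = r)
    }
    got <- dplyr::bind_rows(reps)
    if (nrow(got) == 0L) next
    out[[s]] <- got |>
      dplyr::mutate(
        scenario = sc$label, family = sc$family, rho = sc$rho,
        is_null = is_null_scenario(sc)
      )
  }
  empty <- tibble::tibble(
    scenario = character(), family = character(), rho = numeric(),
    is_null = logical(), method = character(), replicate = integer(),
    p_value = numeric(), redraws = integer()
  )
  dplyr::bind_rows(c(list(empty), out)) |>
    dplyr::select("scenario", "family", "rho", "is_null", "method",
                  "replicate", "p_value", "redraws")
}

#' Per-scenario rejection table from replicate rows
#'
#' @param replicate_rows Output of [run_study()].
#' @param alpha Significance level.
#' @return A tibble: `scenario`, `family`, `rho`, `is_null`, `method`,
#'   `rate`, `se`, `n_reps`.
#' @export
rejection_table <- function(replicate_rows, alpha = 0.05) {
  replicate_rows |>
    dplyr::group_by(.data$scenario, .data$family, .data$rho, .data$is_null,
                    .data$method) |>
    dplyr::summarise(
      rate = mean(.data$p_value < alpha),
      se = sqrt(rate * (1 - rate) / dplyr::n()),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

paired_md <- function(ref, other) {
  d <- ref - other
  n <- length(d)
  md <- mean(d)
  if (n < 2 || sd(d) == 0) {
    return(list(md = md, lo = md, hi = md, degenerate = TRUE))
  }
  tq <- qt(0.975, df = n - 1)
  half <- tq * sd(d) / sqrt(n)
  list(md = md, lo = md - half, hi = md + half, degenerate = FALSE)
}

#' Aggregate a replicate study into a method comparison report
#'
#' Reproduces the shape of a power-comparison table: per method, the mean
#' power over non-null scenarios (identical to the area under the 1-ECDF
#' curve of per-scenario powers), a t-based 95% CI over scenarios, and the
#' mean difference (MD) versus a reference method with a paired-t 95% CI —
#' overall and stratified by correlation and by scenario family.
#'
#' @param replicate_rows Output of [run_study()] (needs >= 2 non-null
#'   scenarios for the paired t).
#' @param reference_method Reference for mean differences (default
#'   `"CLMM-Bootstrap"`).
#' @param alpha Significance level defining rejection.
#' @return An object of class `propower_report`: a list with `rejection`
#'   (per-scenario rates), `aggregation` (per-stratum method summaries) and
#'   `alpha`.
#' @export
aggregate_report <- function(replicate_rows,
                             reference_method = "CLMM-Bootstrap",
                             alpha = 0.05) {
  rej <- rejection_table(replicate_rows, alpha)
  if (!reference_method %in% rej$method) {
    stop(sprintf("reference method '%s' absent from results", reference_method),
         call. = FALSE)
  }
  pow <- rej[!rej$is_null, ]
  if (nrow(pow) == 0L) stop("no non-null scenarios to aggregate", call. = FALSE)

  strata <- list(list(name = "overall", rows = pow))
  for (r in sort(unique(pow$rho))) {
    strata[[length(strata) + 1L]] <-
      list(name = sprintf("rho=%.1f", r), rows = pow[pow$rho == r, ])
  }
  for (f in sort(unique(pow$family))) {
    strata[[length(strata) + 1L]] <-
      list(name = sprintf("family=%s", f), rows = pow[pow$family == f, ])
  }

  agg <- purrr::map_dfr(strata, function(st) {
    wide <- st$rows |>
      dplyr::select("scenario", "method", "rate") |>
      tidyr::pivot_wider(names_from = "method", values_from = "rate")
    ref <- wide[[reference_method]]
    purrr::map_dfr(setdiff(names(wide), "scenario"), function(mth) {
      pwr <- wide[[mth]]
      n <- length(pwr)
      ci <- if (n >= 2 && sd(pwr) > 0) {
        mean(pwr) + c(-1, 1) * qt(0.975, n - 1) * sd(pwr) / sqrt(n)
      } else c(mean(pwr), mean(pwr))
      mdres <- paired_md(ref, pwr)
      tibble::tibble(
        stratum = st$name, method = mth, n_scenarios = n,
        mean_power = mean(pwr), power_lo = ci[1], power_hi = ci[2],
        md = mdres$md, md_lo = mdres$lo, md_hi = mdres$hi,
        is_reference = mth == reference_method
      )
    })
  })
  structure(list(rejection = rej, aggregation = agg, alpha = alpha,
                 reference_method = reference_method),
            class = "propower_report")
}

#' @export
print.propower_report <- function(x, ...) {
  cat(sprintf("<simulation report> alpha = %g, reference = %s\n",
              x$alpha, x$reference_method))
  ov <- x$aggregation[x$aggregation$stratum == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-14s mean power %5.1f%%  [%5.1f%%, %5.1f%%]  MD %+5.2f%%\n",
                ov$method[i], 100 * ov$mean_power[i], 100 * ov$power_lo[i],
                100 * ov$power_hi[i], 100 * ov$md[i]))
  }
  invisible(x)
}

#' Area under a 1-ECDF power curve
#'
#' For a set of per-scenario power estimates, the area under one minus their
#' empirical cumulative distribution function over `[0, 1]` equals their
#' arithmetic mean exactly (step-function integration), which is why the
#' report's mean power doubles as the 1-ECDF area.
#'
#' @param powers Numeric vector of per-scenario power estimates in `[0, 1]`.
#' @return The area (= mean power).
#' @export
ecdf_area <- function(powers) {
  stopifnot(all(powers >= 0 & powers <= 1))
  mean(powers)
}
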