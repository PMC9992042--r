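#' @useDynLib propower, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats plogis qlogis rnorm runif qnorm pnorm pchisq pnorm pt qt
#'   sd t.test integrate optimize
#' @importFrom generics tidy glance
NULL

SCENARIO_FAMILIES <- c(
  "null_equal_all_times",
  "equal_baseline_diff_followup",
  "diff_baseline_same_increments",
  "b35_like",
  "diff_all_times"
)

#' Define a simulation scenario
#'
#' A scenario fixes everything the copula simulator needs for one two-arm
#' design cell: the per-arm, per-time marginal category probabilities of a
#' single adverse-event item, the exchangeable within-patient latent
#' correlation, and the arm size. Time 1 is the baseline assessment.
#'
#' @param label Character identifier, unique within a grid.
#' @param family Scenario family, one of
#'   `"null_equal_all_times"`, `"equal_baseline_diff_followup"`,
#'   `"diff_baseline_same_increments"`, `"b35_like"`, `"diff_all_times"`.
#' @param marginals List of two elements (arm 0, arm 1); each a list of
#'   `n_times` numeric probability vectors of length `n_categories`, one per
#'   time point, each summing to 1.
#' @param rho Within-patient latent correlation, in `[0, 1)`.
#' @param n_per_arm Patients per arm (>= 2).
#'
#' @return An object of class `propower_scenario`.
#' @export
scenario <- function(label, family, marginals, rho, n_per_arm = 100L) {
  sc <- structure(
    list(
      label = as.character(label),
      family = as.character(family),
      marginals = lapply(marginals, function(arm) lapply(arm, as.numeric)),
      rho = as.numeric(rho),
      n_per_arm = as.integer(n_per_arm),
      n_times = length(marginals[[1]]),
      n_categories = length(marginals[[1]][[1]])
    ),
    class = "propower_scenario"
  )
  validate_scenario(sc)
  sc
}

#' Validate a scenario object
#'
#' Checks probability normalisation, dimensional consistency, correlation
#' range, arm size, and the structural constraints the family label implies
#' (e.g. a null family must have identical marginals in both arms at every
#' time point).
#'
#' @param sc A `propower_scenario`.
#' @return `sc`, invisibly, if valid; otherwise an error naming the scenario
#'   and offending arm/time.
#' @export
validate_scenario <- function(sc) {
  lab <- sc$label
  if (!sc$family %in% SCENARIO_FAMILIES) {
    stop(sprintf("scenario '%s': unknown family '%s'", lab, sc$family),
         call. = FALSE)
  }
  if (length(sc$marginals) != 2L) {
    stop(sprintf("scenario '%s': marginals must cover exactly arms 0 and 1", lab),
         call. = FALSE)
  }
  if (sc$n_times < 2L) {
    stop(sprintf("scenario '%s': need at least 2 time points", lab), call. = FALSE)
  }
  if (sc$n_categories < 2L) {
    stop(sprintf("scenario '%s': need at least 2 categories", lab), call. = FALSE)
  }
  for (a in 1:2) {
    arm <- sc$marginals[[a]]
    if (length(arm) != sc$n_times) {
      stop(sprintf("scenario '%s' arm %d: expected %d time points, got %d",
                   lab, a - 1L, sc$n_times, length(arm)), call. = FALSE)
    }
    for (t in seq_along(arm)) {
      p <- arm[[t]]
      if (length(p) != sc$n_categories) {
        stop(sprintf("scenario '%s' arm %d time %d: expected %d categories",
                     lab, a - 1L, t, sc$n_categories), call. = FALSE)
      }
      if (any(p < 0)) {
        stop(sprintf("scenario '%s' arm %d time %d: negative probability",
                     lab, a - 1L, t), call. = FALSE)
      }
      if (abs(sum(p) - 1) > 1e-12) {
        stop(sprintf("scenario '%s' arm %d time %d: probabilities sum to %.15g, not 1",
                     lab, a - 1L, t, sum(p)), call. = FALSE)
      }
    }
  }
  if (!(sc$rho >= 0 && sc$rho < 1)) {
    stop(sprintf("scenario '%s': rho must lie in [0, 1)", lab), call. = FALSE)
  }
  if (sc$n_per_arm < 2L) {
    stop(sprintf("scenario '%s': n_per_arm must be >= 2", lab), call. = FALSE)
  }
  same_at <- function(t) {
    isTRUE(all.equal(sc$marginals[[1]][[t]], sc$marginals[[2]][[t]],
                     tolerance = 1e-12))
  }
  if (sc$family == "null_equal_all_times" &&
      !all(vapply(seq_len(sc$n_times), same_at, logical(1)))) {
    stop(sprintf("scenario '%s': null family requires identical marginals in both arms at every time", lab),
         call. = FALSE)
  }
  if (sc$family == "equal_baseline_diff_followup") {
    if (!same_at(1L)) {
      stop(sprintf("scenario '%s': family requires identical baseline marginals", lab),
           call. = FALSE)
    }
    if (all(vapply(2:sc$n_times, same_at, logical(1)))) {
      stop(sprintf("scenario '%s': family requires an arm difference at some follow-up time", lab),
           call. = FALSE)
    }
  }
  invisible(sc)
}

#' @export
print.propower_scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'>  family: %s\n", x$label, x$family))
  cat(sprintf("  n_per_arm: %d, times: %d (time 1 = baseline), categories: 0..%d, rho: %.2f\n",
              x$n_per_arm, x$n_times, x$n_categories - 1L, x$rho))
  for (a in 1:2) {
    for (t in seq_len(x$n_times)) {
      cat(sprintf("  arm %d t%d: %s\n", a - 1L, t,
                  paste(formatC(x$marginals[[a]][[t]], format = "f", digits = 3),
                        collapse = " ")))
    }
  }
  invisible(x)
}

#' Shift a categorical marginal on the cumulative-logit scale
#'
#' Moves probability mass from lower to higher categories by subtracting
#' `shift` from every cumulative log-odds `logit P(Y <= k)` — a
#' proportional-odds location shift. `shift = 0` is the identity; positive
#' shifts increase severity.
#'
#' @param p Probability vector over categories `0..K-1`.
#' @param shift Log-odds shift (positive moves mass upward).
#' @return A probability vector of the same length.
#' @export
shift_marginal <- function(p, shift) {
  if (shift == 0) return(p)
  cum <- cumsum(p)
  K <- length(p)
  inner <- pmin(pmax(cum[-K], 1e-12), 1 - 1e-12)
  new_cum <- c(plogis(qlogis(inner) - shift), 1)
  out <- diff(c(0, new_cum))
  out / sum(out)
}

# Base marginals used by the built-in grid. `base` is a typical
# moderate-severity AE item; `skew` mimics the strongly zero-inflated
# distributions seen for most trial symptom items.
grid_base_marginal <- function() c(0.55, 0.20, 0.12, 0.08, 0.05)
grid_skew_marginal <- function() c(0.70, 0.15, 0.08, 0.05, 0.02)

build_family_marginals <- function(family,
                                   base = grid_base_marginal(),
                                   skew = grid_skew_marginal(),
                                   effect = 0.5,
                                   trend = 0.25,
                                   n_times = 3L) {
  ts <- seq_len(n_times)
  const <- function(p) lapply(ts, function(t) p)
  switch(
    family,
    null_equal_all_times = list(const(base), const(base)),
    equal_baseline_diff_followup = list(
      const(base),
      lapply(ts, function(t) if (t == 1L) base else shift_marginal(base, effect))
    ),
    diff_baseline_same_increments = list(
      lapply(ts, function(t) shift_marginal(base, trend * (t - 1L))),
      lapply(ts, function(t) shift_marginal(base, effect + trend * (t - 1L)))
    ),
    b35_like = list(
      const(skew),
      lapply(ts, function(t) if (t == 1L) skew else shift_marginal(skew, effect))
    ),
    diff_all_times = list(
      const(base),
      const(shift_marginal(base, effect))
    ),
    stop(sprintf("unknown family '%s'", family), call. = FALSE)
  )
}

#' Built-in scenario grid
#'
#' A deterministic grid covering the five scenario families at latent
#' correlations 0.2, 0.5 and 0.9, with 100 patients per arm, three time
#' points (time 1 = baseline) and five categories (0-4). Arm differences are
#' proportional-odds shifts of a common base marginal: `effect` log-odds
#' between arms where the family calls for a difference, `trend` log-odds
#' per follow-up time for the family with a shared time trend.
#'
#' @param rhos Correlations to span (default `c(0.2, 0.5, 0.9)`).
#' @param n_per_arm Patients per arm (default 100).
#' @param effect Between-arm log-odds shift (default 0.5).
#' @param trend Per-time log-odds trend for the shared-increment family
#'   (default 0.25).
#' @return A list of `propower_scenario` objects (families x correlations).
#' @export
default_grid <- function(rhos = c(0.2, 0.5, 0.9), n_per_arm = 100L,
                         effect = 0.5, trend = 0.25) {
  out <- list()
  for (fam in SCENARIO_FAMILIES) {
    marg <- build_family_marginals(fam, effect = effect, trend = trend)
    for (r in rhos) {
      lab <- sprintf("%s_rho%02.0f", fam, 100 * r)
      out[[lab]] <- scenario(lab, fam, marg, rho = r, n_per_arm = n_per_arm)
    }
  }
  unname(out)
}

#' Is a scenario null?
#'
#' @param sc A `propower_scenario`.
#' @return `TRUE` if both arms share identical marginals at every time point.
#' @export
is_null_scenario <- function(sc) {
  all(vapply(seq_len(sc$n_times), function(t) {
    isTRUE(all.equal(sc$marginals[[1]][[t]], sc$marginals[[2]][[t]],
                     tolerance = 1e-12))
  }, logical(1)))
}

scenario_to_entry <- function(sc) {
  list(
    label = sc$label,
    family = sc$family,
    rho = sc$rho,
    n_per_arm = sc$n_per_arm,
    marginals = lapply(sc$marginals, function(arm) lapply(arm, identity))
  )
}

entry_to_scenario <- function(e) {
  need <- c("label", "family", "rho", "n_per_arm", "marginals")
  miss <- setdiff(need, names(e))
  if (length(miss)) {
    stop(sprintf("scenario entry %s: missing field(s) %s",
                 if (is.null(e$label)) "<unlabelled>" else sprintf("'%s'", e$label),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  scenario(e$label, e$family, e$marginals, rho = e$rho, n_per_arm = e$n_per_arm)
}

#' Load scenarios from a YAML or JSON configuration
#'
#' The configuration holds a top-level list `scenarios`; each entry supplies
#' `label`, `family`, `rho`, `n_per_arm` and `marginals` (arm, then time,
#' then a length-K probability vector). The same schema is accepted in YAML
#' and JSON; the dialect is inferred from the file extension (`.json` means
#' JSON, anything else is parsed as YAML, of which JSON is a subset).
#'
#' @param path Path to the configuration file.
#' @return A list of validated `propower_scenario` objects, in file order.
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$scenarios)) {
    stop("configuration must contain a top-level 'scenarios' list", call. = FALSE)
  }
  lapply(cfg$scenarios, entry_to_scenario)
}

#' Write scenarios to a YAML or JSON configuration
#'
#' Inverse of [load_scenarios()]: serialising and re-loading reproduces the
#' scenario list exactly.
#'
#' @param scenarios List of `propower_scenario` objects.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  cfg <- list(scenarios = lapply(scenarios, scenario_to_entry))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15L)
  }
  invisible(path)
}

#' Tabulate a scenario list
#'
#' @param scenarios List of `propower_scenario` objects.
#' @return A tibble with one row per scenario (label, family, rho, n_per_arm,
#'   n_times, n_categories, is_null).
#' @export
scenario_summary <- function(scenarios) {
  tibble::tibble(
    label = vapply(scenarios, `[[`, character(1), "label"),
    family = vapply(scenarios, `[[`, character(1), "family"),
    rho = vapply(scenarios, `[[`, numeric(1), "rho"),
    n_per_arm = vapply(scenarios, `[[`, integer(1), "n_per_arm"),
    n_times = vapply(scenarios, `[[`, integer(1), "n_times"),
    n_categories = vapply(scenarios, `[[`, integer(1), "n_categories"),
    is_null = vapply(scenarios, is_null_scenario, logical(1))
  )
}
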