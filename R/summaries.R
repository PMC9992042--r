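#' Toxicity index of a grade vector
#'
#' Order-sensitive summary of adverse-event grades that refines the maximum
#' grade with discounted lower grades. With grades sorted descending
#' `g(1) >= g(2) >= ...`, the index is
#' `TI = sum_i g(i) * prod_{j<i} 1/(1 + g(j))` (empty product = 1), so the
#' integer part of TI equals the maximum grade and repeated lower-grade
#' events break ties between patients sharing the same maximum.
#'
#' @param grades Integer vector of grades in `0..max_grade`.
#' @param max_grade Largest admissible grade (default 4, PRO-CTCAE scale).
#' @return A single non-negative number in `[0, max_grade + 1)`.
#' @export
#' @examples
#' toxicity_index(c(3, 2, 1))  # 3 + 2/4 + 1/12 = 3.5833...
toxicity_index <- function(grades, max_grade = 4L) {
  check_grades(grades, max_grade)
  g <- sort(grades, decreasing = TRUE)
  sum(g * cumprod(c(1, 1 / (1 + g[-length(g)]))))
}

check_grades <- function(grades, max_grade) {
  if (length(grades) == 0L) stop("empty grade vector", call. = FALSE)
  if (any(is.na(grades)) || any(grades != floor(grades)) ||
      any(grades < 0) || any(grades > max_grade)) {
    stop(sprintf("grades must be integers in 0..%d", max_grade), call. = FALSE)
  }
  invisible(grades)
}

#' Baseline-adjust follow-up grades
#'
#' Keeps a follow-up grade only when it exceeds the baseline grade by at
#' least 1; all other follow-ups are set to 0. If no follow-up exceeds the
#' baseline, every summary of the adjusted vector is therefore 0.
#'
#' @param baseline Baseline grade (single integer).
#' @param followups Integer vector of follow-up grades.
#' @param max_grade Largest admissible grade.
#' @return An integer vector of the same length as `followups`.
#' @export
baseline_adjust <- function(baseline, followups, max_grade = 4L) {
  check_grades(baseline, max_grade)
  check_grades(followups, max_grade)
  ifelse(followups >= baseline + 1L, followups, 0L)
}

#' Summarise one patient's follow-up grades
#'
#' Applies one of the three summary measures (TI, Avg, Max) to either the
#' raw follow-up grades (`post_baseline` strategy, baseline then enters
#' downstream models as a covariate) or to the baseline-adjusted grades
#' (`baseline_adjusted` strategy).
#'
#' @param baseline Baseline grade.
#' @param followups Follow-up grade vector.
#' @param measure `"TI"`, `"Avg"` or `"Max"`.
#' @param strategy `"post_baseline"` or `"baseline_adjusted"`.
#' @param max_grade Largest admissible grade.
#' @return The summary value (single number).
#' @export
summarize_patient <- function(baseline, followups,
                              measure = c("TI", "Avg", "Max"),
                              strategy = c("post_baseline", "baseline_adjusted"),
                              max_grade = 4L) {
  measure <- match.arg(measure)
  strategy <- match.arg(strategy)
  g <- if (strategy == "baseline_adjusted") {
    baseline_adjust(baseline, followups, max_grade)
  } else {
    check_grades(followups, max_grade)
    followups
  }
  switch(measure,
         TI = toxicity_index(g, max_grade),
         Avg = mean(g),
         Max = max(g))
}

#' Per-patient summary table for a panel
#'
#' Batch version of [summarize_patient()]: takes a long-format panel (time 1
#' = baseline, times >= 2 = follow-ups) and returns one row per patient x
#' measure x strategy.
#'
#' @param panel Long-format panel tibble (`patient_id`, `arm`, `time`,
#'   `score`).
#' @param measures Subset of `c("TI", "Avg", "Max")`.
#' @param strategies Subset of `c("post_baseline", "baseline_adjusted")`.
#' @param max_grade Largest admissible grade.
#' @return A tibble with columns `patient_id`, `arm`, `baseline`, `measure`,
#'   `strategy`, `value`.
#' @export
summarize_panel <- function(panel,
                            measures = c("TI", "Avg", "Max"),
                            strategies = c("post_baseline", "baseline_adjusted"),
                            max_grade = 4L) {
  wide <- panel |>
    dplyr::arrange(.data$patient_id, .data$time)
  base <- wide[wide$time == 1L, c("patient_id", "arm", "score")]
  names(base)[3] <- "baseline"
  fu <- wide[wide$time >= 2L, ]
  fu_split <- split(fu$score, factor(fu$patient_id, levels = unique(wide$patient_id)))
  base <- base[match(names(fu_split), as.character(base$patient_id)), ]
  grid <- tidyr::expand_grid(measure = measures, strategy = strategies)
  purrr::pmap_dfr(grid, function(measure, strategy) {
    meas <- measure
    strat <- strategy
    vals <- vapply(seq_along(fu_split), function(i) {
      summarize_patient(base$baseline[i], fu_split[[i]], meas, strat, max_grade)
    }, numeric(1))
    tibble::tibble(
      patient_id = base$patient_id,
      arm = base$arm,
      baseline = base$baseline,
      measure = meas,
      strategy = strat,
      value = vals
    )
  })
}
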