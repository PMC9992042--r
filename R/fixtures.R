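#' Deterministic toy panel
#'
#' Six patients (three per arm), three time points, literal scores chosen to
#' cover the hand-checkable corners: ties between follow-ups, zero
#' baselines, a follow-up at the maximum grade, and a patient whose
#' follow-ups never exceed baseline (so every baseline-adjusted summary is
#' zero). Stable across releases; used in examples and regression tests.
#'
#' @return A long-format panel tibble.
#' @export
make_toy_panel <- function() {
  # patient: baseline, followup t2, followup t3
  scores <- rbind(
    c(1L, 3L, 1L),  # arm 0: adjusted (3, 0), TI 3
    c(0L, 2L, 2L),  # arm 0: tie between follow-ups
    c(2L, 2L, 1L),  # arm 0: never exceeds baseline -> adjusted all 0
    c(0L, 4L, 1L),  # arm 1: max-grade follow-up
    c(0L, 0L, 0L),  # arm 1: all zero
    c(1L, 2L, 3L)   # arm 1: monotone worsening
  )
  tibble::tibble(
    patient_id = rep(1:6, each = 3L),
    arm = rep(c(0L, 0L, 0L, 1L, 1L, 1L), each = 3L),
    time = rep(1:3, times = 6L),
    score = as.integer(t(scores))
  )
}

#' Registry of built-in fixtures
#'
#' Each fixture carries the expected values of the operations it exercises,
#' a provenance tag (`trivial` for by-construction facts, `derived` for
#' values computed with an independent oracle named in `oracle`) and a
#' comparison tolerance.
#'
#' @return A named list of fixtures.
#' @export
fixture_registry <- function() {
  list(
    toy_summaries = list(
      name = "toy_summaries",
      panel = make_toy_panel(),
      tolerance = 1e-12,
      expected = tibble::tibble(
        operation = c("TI_ba_patient1", "Max_pb_patient4", "Avg_pb_patient2",
                      "TI_ba_patient3", "TI_pb_patient6"),
        value = c(3, 4, 2, 0, 3 + 2 / 4),
        provenance = c("derived", "trivial", "trivial", "trivial", "derived"),
        oracle = c("hand evaluation of the sorted-product formula", "", "",
                   "", "hand evaluation of the sorted-product formula")
      )
    )
  )
}

compute_fixture_values <- function(fx) {
  summ <- summarize_panel(fx$panel)
  pick <- function(pid, meas, strat) {
    summ$value[summ$patient_id == pid & summ$measure == meas &
                 summ$strategy == strat]
  }
  tibble::tibble(
    operation = c("TI_ba_patient1", "Max_pb_patient4", "Avg_pb_patient2",
                  "TI_ba_patient3", "TI_pb_patient6"),
    got = c(pick(1, "TI", "baseline_adjusted"),
            pick(4, "Max", "post_baseline"),
            pick(2, "Avg", "post_baseline"),
            pick(3, "TI", "baseline_adjusted"),
            pick(6, "TI", "post_baseline"))
  )
}

#' Run a fixture against its golden file
#'
#' Recomputes the fixture's mapped operations, compares them with the golden
#' CSV under `golden_dir`, and returns a diff report naming each operation,
#' its expected and obtained value and the provenance of the expectation.
#' Golden files are rewritten only under explicit opt-in (`refresh = TRUE`).
#'
#' @param name Fixture name (see [fixture_registry()]).
#' @param golden_dir Directory holding golden CSVs.
#' @param refresh Rewrite the golden file from the current computation.
#' @return A tibble: `operation`, `expected`, `got`, `provenance`, `pass`.
#' @export
golden_run <- function(name, golden_dir, refresh = FALSE) {
  reg <- fixture_registry()
  fx <- reg[[name]]
  if (is.null(fx)) stop(sprintf("no fixture '%s'", name), call. = FALSE)
  got <- compute_fixture_values(fx)
  path <- file.path(golden_dir, paste0(name, ".csv"))
  if (refresh || !file.exists(path)) {
    if (!refresh) stop(sprintf("golden file missing: %s (run with refresh = TRUE)", path),
                       call. = FALSE)
    utils::write.csv(data.frame(operation = got$operation, value = got$got),
                     path, row.names = FALSE, quote = FALSE)
  }
  gold <- utils::read.csv(path)
  exp <- fx$expected
  merged <- dplyr::left_join(exp, got, by = "operation") |>
    dplyr::left_join(tibble::tibble(operation = gold$operation,
                                    golden = gold$value), by = "operation")
  merged |>
    dplyr::mutate(pass = abs(.data$got - .data$value) <= fx$tolerance &
                    abs(.data$got - .data$golden) <= fx$tolerance) |>
    dplyr::select("operation", expected = "value", "got", "golden",
                  "provenance", "pass")
}
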