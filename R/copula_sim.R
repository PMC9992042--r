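#' Simulate a correlated ordinal panel from a scenario
#'
#' Draws, for each patient, a latent multivariate normal vector with unit
#' variances and exchangeable correlation `rho` across the time points, maps
#' it to the uniform scale through the normal CDF, and discretises each
#' coordinate into the category whose cumulative-probability cell
#' `[C[k-1], C[k])` contains it, with cells built from that arm and time's
#' marginal. This is a Gaussian copula with multinomial marginals: category
#' frequencies match the scenario marginals exactly in expectation while the
#' latent correlation induces within-patient dependence (the manifest rank
#' correlation is attenuated by discretisation).
#'
#' @param sc A `propower_scenario`.
#' @param seed Integer seed; the same `(scenario, seed)` pair yields a
#'   bit-identical panel.
#' @return A tibble in long format with columns `patient_id`, `arm`, `time`,
#'   `score`, carrying attributes `scenario_label` and `seed`.
#' @export
simulate_panel <- function(sc, seed) {
  validate_scenario(sc)
  if (sc$rho >= 1) stop("rho must be < 1: latent correlation is singular", call. = FALSE)
  set.seed(as.integer(seed))
  n <- sc$n_per_arm
  Tt <- sc$n_times
  K <- sc$n_categories
  N <- 2L * n
  arm <- rep(c(0L, 1L), each = n)
  # exchangeable latent normal: Z_t = sqrt(rho) W + sqrt(1-rho) E_t
  W <- rnorm(N)
  Z <- sqrt(sc$rho) * W + sqrt(1 - sc$rho) * matrix(rnorm(N * Tt), N, Tt)
  U <- pnorm(Z)
  score <- matrix(0L, N, Tt)
  for (a in 0:1) {
    rows <- which(arm == a)
    for (t in seq_len(Tt)) {
      cum <- cumsum(sc$marginals[[a + 1L]][[t]])
      score[rows, t] <- findInterval(U[rows, t], cum[-K])
    }
  }
  tibble::tibble(
    patient_id = rep(seq_len(N), times = Tt),
    arm = rep(arm, times = Tt),
    time = rep(seq_len(Tt), each = N),
    score = as.integer(score)
  ) |>
    dplyr::arrange(.data$patient_id, .data$time) |>
    structure(scenario_label = sc$label, seed = as.integer(seed))
}

panel_dims <- function(panel) {
  list(
    n_times = length(unique(panel$time)),
    n_patients = length(unique(panel$patient_id))
  )
}

#' Check a panel against the redraw rule
#'
#' A simulated sample is admissible only if the modelled responses show
#' variation: pooling all follow-up observations (time >= 2) within each arm,
#' at least two distinct categories must appear in both arms. Degenerate
#' samples are redrawn by [simulate_admissible()] so that simulation results
#' are not driven by unfittable datasets.
#'
#' @param panel Long-format panel tibble (`patient_id`, `arm`, `time`,
#'   `score`).
#' @return `TRUE` if admissible, `FALSE` otherwise.
#' @export
validate_panel <- function(panel) {
  fu <- panel[panel$time >= 2L, ]
  for (a in 0:1) {
    if (length(unique(fu$score[fu$arm == a])) < 2L) return(FALSE)
  }
  TRUE
}

#' Simulate a panel, redrawing until admissible
#'
#' Calls [simulate_panel()] with `seed`, `seed + 1`, ... until
#' [validate_panel()] passes, so the redraw policy itself is reproducible.
#'
#' @inheritParams simulate_panel
#' @param max_redraws Maximum number of redraws before giving up.
#' @return An admissible panel with an extra attribute `redraws` counting the
#'   discarded draws.
#' @export
simulate_admissible <- function(sc, seed, max_redraws = 100L) {
  stopifnot(max_redraws >= 1L)
  for (k in 0:max_redraws) {
    panel <- simulate_panel(sc, seed + k)
    if (validate_panel(panel)) {
      attr(panel, "redraws") <- k
      return(panel)
    }
  }
  stop(sprintf("scenario '%s': no admissible panel within %d redraws",
               sc$label, max_redraws), call. = FALSE)
}

#' Write a panel to CSV
#'
#' Long format, one row per observation (`patient_id`, `arm`, `time`,
#' `score`); the same layout is accepted for user-supplied real data.
#'
#' @param panel Panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel)[, c("patient_id", "arm", "time", "score")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a panel from CSV
#'
#' @param path Path to a long-format panel CSV with columns `patient_id`,
#'   `arm`, `time`, `score`.
#' @return A panel tibble.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path)
  need <- c("patient_id", "arm", "time", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("panel file lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(
      arm = as.integer(.data$arm),
      time = as.integer(.data$time),
      score = as.integer(.data$score)
    ) |>
    dplyr::arrange(.data$patient_id, .data$time)
}
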