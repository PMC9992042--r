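test_that("Monte-Carlo band matches the closed form", {
  band <- mc_ci_band(0.05, 1000)
  expect_equal(round(unname(band), 4), c(0.0365, 0.0635))
  wide <- mc_ci_band(0.5, 100)
  expect_equal(unname(wide), 0.5 + c(-1, 1) * 0.098, tolerance = 1e-3)
  tiny <- mc_ci_band(0.05, 1e9)
  expect_lt(diff(tiny), 1e-4)
  expect_equal(mean(tiny), 0.05)
  expect_error(mc_ci_band(0, 100))
})

test_that("replicate seeds are deterministic, spread out, and in range", {
  s1 <- vapply(1:500, function(r) replicate_seed(1, "scenA", r), integer(1))
  s2 <- vapply(1:500, function(r) replicate_seed(1, "scenB", r), integer(1))
  expect_identical(s1, vapply(1:500, function(r) replicate_seed(1, "scenA", r),
                              integer(1)))
  expect_lt(length(intersect(s1, s2)), 5)
  expect_equal(anyDuplicated(s1), 0)
  expect_true(all(s1 > 0 & s1 < 2^31))
})

test_that("one replicate returns a p-value per method, deterministically", {
  sc <- null_scenario(rho = 0.2, n_per_arm = 60L)
  methods <- setdiff(all_methods(), "CLMM-Bootstrap")
  r1 <- run_replicate(sc, methods, seed = 42, n_boot = 10)
  r2 <- run_replicate(sc, methods, seed = 42, n_boot = 10)
  expect_identical(r1, r2)
  expect_setequal(r1$method, methods)
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1))
  r3 <- run_replicate(sc, methods, seed = 43, n_boot = 10)
  expect_false(identical(r1$p_value, r3$p_value))
})

test_that("an extreme treatment effect is detected by all eight methods", {
  p0 <- c(0.7, 0.15, 0.08, 0.05, 0.02)
  p_shift <- c(0.02, 0.03, 0.05, 0.2, 0.7)
  sc <- scenario("huge", "equal_baseline_diff_followup",
                 list(replicate(3, p0, simplify = FALSE),
                      list(p0, p_shift, p_shift)),
                 rho = 0.5, n_per_arm = 100L)
  r <- run_replicate(sc, all_methods(), seed = 7, n_boot = 99)
  expect_equal(nrow(r), 8L)
  expect_true(all(r$p_value < 0.05))
})

test_that("rejection estimation handles edge replicate counts", {
  sc <- null_scenario(rho = 0.2, n_per_arm = 50L)
  out <- estimate_rejection(sc, "PIM-BA-Max", n_reps = 1, master_seed = 3)
  expect_true(out$rate %in% c(0, 1))
  expect_equal(out$n_used, 1L)
  out5 <- estimate_rejection(sc, c("PIM-BA-Max", "CLMM"), n_reps = 5,
                             master_seed = 3)
  expect_equal(nrow(out5), 2L)
  expect_true(all(out5$rate >= 0 & out5$rate <= 1))
  expect_equal(out5$se, sqrt(out5$rate * (1 - out5$rate) / out5$n_used))
})

test_that("a scenario whose replicates all fail raises an estimation error", {
  p_deg <- c(1, 0, 0, 0, 0)
  sc <- scenario("alldeg", "null_equal_all_times",
                 list(replicate(3, p_deg, simplify = FALSE),
                      replicate(3, p_deg, simplify = FALSE)),
                 rho = 0.2, n_per_arm = 4L)
  expect_error(
    suppressWarnings(estimate_rejection(sc, "PIM-BA-Max", n_reps = 2,
                                        master_seed = 1, max_redraws = 2L)),
    "every replicate failed")
})

test_that("study tables carry scenario metadata and are order-invariant", {
  scs <- list(null_scenario(rho = 0.2, n_per_arm = 40L),
              default_grid(n_per_arm = 40L)[[4]])
  methods <- c("PIM-BA-TI", "PIM-BC-TI")
  rows <- run_study(scs, methods, n_reps = 3, master_seed = 11)
  expect_setequal(unique(rows$method), methods)
  expect_equal(nrow(rows), 2 * 2 * 3)
  rows_flip <- run_study(rev(scs), methods, n_reps = 3, master_seed = 11)
  key <- function(d) d[order(d$scenario, d$method, d$replicate), ]
  expect_equal(key(rows)$p_value, key(rows_flip)$p_value)
  rej <- rejection_table(rows)
  expect_true(all(rej$rate >= 0 & rej$rate <= 1))
  expect_equal(sum(rej$is_null), 2L)  # one null scenario x two methods
})

test_that("the 1-ECDF area is exactly the mean of per-scenario powers", {
  powers <- c(0.2, 0.4, 0.6)
  expect_equal(ecdf_area(powers), 0.4)
  # step-function integration oracle on a fine grid
  grid <- seq(0, 1, by = 1e-4)
  surv <- vapply(grid, function(x) mean(powers > x), numeric(1))
  expect_equal(sum(surv) * 1e-4, mean(powers), tolerance = 1e-3)
  set.seed(8)
  pw <- runif(17)
  surv <- vapply(grid, function(x) mean(pw > x), numeric(1))
  expect_equal(ecdf_area(pw), mean(pw))
  expect_equal(sum(surv) * 1e-4, ecdf_area(pw), tolerance = 1e-3)
})

test_that("aggregation computes paired mean differences against the reference", {
  # fabricated replicate rows: two methods with a constant power gap
  mk <- function(scen, method, rate, rho, fam) {
    tibble::tibble(scenario = scen, family = fam, rho = rho, is_null = FALSE,
                   method = method, replicate = 1:100,
                   p_value = rep(c(0.01, 0.5), round(c(rate, 1 - rate) * 100)),
                   redraws = 0L)
  }
  rows <- dplyr::bind_rows(
    mk("s1", "CLMM-Bootstrap", 0.50, 0.2, "f"),
    mk("s1", "PIM-BC-TI", 0.40, 0.2, "f"),
    mk("s2", "CLMM-Bootstrap", 0.70, 0.5, "f"),
    mk("s2", "PIM-BC-TI", 0.60, 0.5, "f"),
    mk("s3", "CLMM-Bootstrap", 0.30, 0.9, "f"),
    mk("s3", "PIM-BC-TI", 0.20, 0.9, "f")
  )
  rep_out <- aggregate_report(rows, reference_method = "CLMM-Bootstrap")
  ov <- rep_out$aggregation[rep_out$aggregation$stratum == "overall", ]
  expect_equal(ov$mean_power[ov$method == "CLMM-Bootstrap"], 0.5)
  expect_equal(ov$mean_power[ov$method == "PIM-BC-TI"], 0.4)
  md <- ov[ov$method == "PIM-BC-TI", ]
  expect_equal(md$md, 0.1, tolerance = 1e-12)
  # zero paired variance: degenerate CI collapses onto the MD
  expect_equal(md$md_lo, 0.1, tolerance = 1e-12)
  expect_equal(md$md_hi, 0.1, tolerance = 1e-12)
  ref_row <- ov[ov$method == "CLMM-Bootstrap", ]
  expect_equal(ref_row$md, 0)
  expect_true(ref_row$is_reference)
  # strata present
  expect_true(all(c("overall", "rho=0.2", "rho=0.5", "rho=0.9", "family=f")
                  %in% rep_out$aggregation$stratum))
  expect_error(aggregate_report(rows, reference_method = "CLMM"), "absent")
})

test_that("plot helpers return ggplot objects", {
  rej <- tibble::tibble(
    scenario = rep(c("a", "b", "n"), each = 2),
    family = "f", rho = 0.5,
    is_null = rep(c(FALSE, FALSE, TRUE), each = 2),
    method = rep(c("CLMM", "PIM-BC-TI"), 3),
    rate = c(0.5, 0.4, 0.7, 0.6, 0.05, 0.04),
    se = 0.01, n_reps = 100
  )
  expect_s3_class(plot_power_ecdf(rej), "ggplot")
  expect_s3_class(plot_type1(rej), "ggplot")
  expect_error(plot_power_ecdf(rej[rej$is_null, ]), "non-null")
  expect_error(plot_type1(rej[!rej$is_null, ]), "null")
})
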