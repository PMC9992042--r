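test_that("degenerate marginals yield constant panels", {
  p <- c(0, 0, 1, 0, 0)
  sc <- scenario("degen", "null_equal_all_times",
                 list(replicate(3, p, simplify = FALSE),
                      replicate(3, p, simplify = FALSE)),
                 rho = 0.5, n_per_arm = 10L)
  panel <- simulate_panel(sc, 1)
  expect_true(all(panel$score == 2L))
  expect_equal(nrow(panel), 10L * 2L * 3L)
})

test_that("panels are reproducible in seed and scenario", {
  sc <- null_scenario(rho = 0.5, n_per_arm = 50L)
  expect_identical(simulate_panel(sc, 7)$score, simulate_panel(sc, 7)$score)
  expect_false(identical(simulate_panel(sc, 7)$score, simulate_panel(sc, 8)$score))
})

test_that("simulated category frequencies match the marginals", {
  p0 <- c(0.5, 0.3, 0.1, 0.07, 0.03)
  sc <- scenario("fid", "null_equal_all_times",
                 list(replicate(3, p0, simplify = FALSE),
                      replicate(3, p0, simplify = FALSE)),
                 rho = 0, n_per_arm = 50000L)
  panel <- simulate_panel(sc, 99)
  cell <- panel[panel$arm == 0 & panel$time == 1, ]
  n <- nrow(cell)
  emp <- tabulate(cell$score + 1L, nbins = 5L) / n
  # within 3 binomial standard errors per category
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(emp - p0) <= 3 * se))
})

test_that("marginal fidelity passes a chi-square goodness-of-fit screen", {
  p0 <- c(0.55, 0.2, 0.12, 0.08, 0.05)
  sc <- scenario("gof", "null_equal_all_times",
                 list(replicate(3, p0, simplify = FALSE),
                      replicate(3, p0, simplify = FALSE)),
                 rho = 0.5, n_per_arm = 50000L)
  panel <- simulate_panel(sc, 123)
  for (a in 0:1) for (t in 1:3) {
    cell <- panel$score[panel$arm == a & panel$time == t]
    obs <- tabulate(cell + 1L, nbins = 5L)
    pv <- suppressWarnings(stats::chisq.test(obs, p = p0)$p.value)
    expect_gt(pv, 0.001)
  }
})

test_that("latent correlation maps to the discretized rank correlation", {
  p0 <- c(0.5, 0.3, 0.1, 0.07, 0.03)
  sc <- scenario("sp", "null_equal_all_times",
                 list(replicate(3, p0, simplify = FALSE),
                      replicate(3, p0, simplify = FALSE)),
                 rho = 0.9, n_per_arm = 50000L)
  panel <- simulate_panel(sc, 11)
  wide <- tidyr::pivot_wider(panel, names_from = "time", values_from = "score",
                             names_prefix = "t")
  emp <- cor(wide$t1, wide$t2, method = "spearman")
  theo <- discretized_spearman(p0, 0.9)
  expect_lt(theo, 0.9)  # attenuation by discretization
  expect_equal(emp, theo, tolerance = 0.02)
})

test_that("within-patient association is monotone in rho", {
  p0 <- c(0.5, 0.3, 0.1, 0.07, 0.03)
  rk <- vapply(c(0.2, 0.5, 0.9), function(r) {
    sc <- scenario("mono", "null_equal_all_times",
                   list(replicate(3, p0, simplify = FALSE),
                        replicate(3, p0, simplify = FALSE)),
                   rho = r, n_per_arm = 10000L)
    panel <- simulate_panel(sc, 5)
    wide <- tidyr::pivot_wider(panel, names_from = "time",
                               values_from = "score", names_prefix = "t")
    cor(wide$t2, wide$t3, method = "spearman")
  }, numeric(1))
  expect_true(all(diff(rk) > 0))
})

test_that("admissibility requires two follow-up categories in each arm", {
  panel <- make_toy_panel()
  expect_true(validate_panel(panel))
  # all follow-ups zero in arm 1
  p2 <- panel
  p2$score[p2$arm == 1 & p2$time >= 2] <- 0L
  expect_false(validate_panel(p2))
  # two categories in follow-ups is enough
  p3 <- panel
  p3$score[p3$arm == 1 & p3$time >= 2] <- c(0L, 1L, 0L, 1L, 0L, 1L)
  expect_true(validate_panel(p3))
  # constant baseline does not matter if follow-ups vary
  p4 <- panel
  p4$score[p4$time == 1] <- 0L
  expect_true(validate_panel(p4))
})

test_that("simulate_admissible redraws deterministically and reports counts", {
  sc <- null_scenario(rho = 0.5, n_per_arm = 50L)
  panel <- simulate_admissible(sc, 3)
  expect_equal(attr(panel, "redraws"), 0L)
  # 0.97 of the mass on category 0: inadmissible draws are common at n = 4
  p_rare <- c(0.97, 0.012, 0.01, 0.005, 0.003)
  sc_rare <- scenario("rare", "null_equal_all_times",
                      list(replicate(3, p_rare, simplify = FALSE),
                           replicate(3, p_rare, simplify = FALSE)),
                      rho = 0.2, n_per_arm = 4L)
  redraws <- vapply(1:40, function(s) {
    attr(simulate_admissible(sc_rare, s * 1000L, max_redraws = 400L), "redraws")
  }, integer(1))
  expect_true(any(redraws >= 1L))
  # degenerate scenario can never be admissible
  p_deg <- c(1, 0, 0, 0, 0)
  sc_deg <- scenario("deg", "null_equal_all_times",
                     list(replicate(3, p_deg, simplify = FALSE),
                          replicate(3, p_deg, simplify = FALSE)),
                     rho = 0.2, n_per_arm = 4L)
  expect_error(simulate_admissible(sc_deg, 1, max_redraws = 1L), "admissible")
})

test_that("panel CSV round-trips", {
  panel <- make_toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(panel))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_panel(bad), "lacks column")
})
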