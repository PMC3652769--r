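test_that("replicate summaries partition classifications and ban twists at P = 1", {
  d <- bin_design(n = 60, p = 1.0, nfac = 2)
  s <- run_replicates(d, n_replicates = 100, seed = 4)
  expect_equal(s$twist_pct, 0)
  expect_equal(s$tie_pct + s$deterministic_pct + s$twist_pct, 100)
  expect_gte(s$prob_overall_imbalance, 0)
  expect_lte(s$prob_overall_imbalance, 1)
  expect_gte(s$prob_factor_imbalance, 0)
  expect_lte(s$prob_factor_imbalance, 1)
  expect_equal(s$n_replicates, 100L)

  d2 <- minim_design(3, 40, 1.0, list(c(0.7, 0.3), c(0.5, 0.3, 0.2)))
  s2 <- run_replicates(d2, n_replicates = 100, seed = 4)
  expect_equal(s2$twist_pct, 0)
  expect_equal(s2$tie_pct + s2$deterministic_pct + s2$twist_pct, 100)
})

test_that("the replicate engine is reproducible under its master seed", {
  d <- minim_design(2, 50, 0.8, list(c(0.5, 0.5), c(0.5, 0.3, 0.2)))
  a <- run_replicates(d, n_replicates = 60, seed = 123)
  b <- run_replicates(d, n_replicates = 60, seed = 123)
  expect_identical(a, b)
  c_ <- run_replicates(d, n_replicates = 60, seed = 124)
  expect_false(identical(a$tie_pct, c_$tie_pct))
})

test_that("engine runs leave the session RNG stream untouched", {
  set.seed(555)
  expected <- runif(1)
  set.seed(555)
  invisible(run_replicates(bin_design(n = 10), n_replicates = 5, seed = 1))
  expect_identical(runif(1), expected)
})

test_that("at P = 0.5 with two arms allocation is marginally uniform", {
  d <- minim_design(2, 1e5, 0.5, c(0.5, 0.5))
  tr <- run_trial(d, seed = 20)
  expect_freq_in_ci99(mean(tr$records$arm == 1L), 0.5, 1e5)
})

test_that("scan_p validates its grid and derives the recommendation fields", {
  d <- bin_design(n = 50, nfac = 2)
  expect_error(scan_p(d, p_grid = numeric(0)), "non-empty")
  expect_error(scan_p(d, p_grid = c(1.0, 0.4)), "0.5")

  sc <- scan_p(d, p_grid = c(0.8, 1.0, 0.6), n_replicates = 40, seed = 2)
  expect_equal(sc$summaries$p_optimal, c(1.0, 0.8, 0.6))  # descending
  expect_equal(sc$summaries$twist_pct[1], 0)               # P = 1 row
  expect_true(all(abs(rowSums(sc$summaries[, c("tie_pct", "deterministic_pct",
                                               "twist_pct")]) - 100) < 1e-9))
})

test_that("the recommended-P rule picks the smallest balanced P above the onset", {
  mk <- function(p, det, bad) data.frame(p_optimal = p,
                                         deterministic_pct = det,
                                         imbalance_verdict = bad)
  grid <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.5)

  # balanced everywhere: recommend the bottom of the grid, no onset
  r <- minimsim:::recommend_p(mk(grid, c(80, 75, 70, 63, 56, 48), rep(FALSE, 6)))
  expect_equal(r$recommended_p, 0.5)
  expect_true(is.na(r$imbalance_onset_p))
  expect_equal(r$predictability_reduction_pct, 80 - 48)

  # onset at 0.6: recommend 0.7
  r2 <- minimsim:::recommend_p(mk(grid, c(80, 75, 70, 63, 56, 48),
                                  c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)))
  expect_equal(r2$recommended_p, 0.7)
  expect_equal(r2$imbalance_onset_p, 0.6)
  expect_equal(r2$predictability_reduction_pct, 17)

  # imbalanced at every P, including the top of the grid
  r3 <- minimsim:::recommend_p(mk(grid, c(80, 75, 70, 63, 56, 48), rep(TRUE, 6)))
  expect_true(r3$no_balanced_p)
  expect_true(is.na(r3$recommended_p))

  # non-monotone noise: the onset is the LARGEST imbalanced P, and an
  # isolated clean verdict below it never tempts the rule downwards
  r4 <- minimsim:::recommend_p(mk(grid, c(80, 75, 70, 63, 56, 48),
                                  c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(r4$imbalance_onset_p, 0.8)
  expect_equal(r4$recommended_p, 0.9)
})

test_that("twist percentage decreases as P rises (shared cohorts)", {
  d <- bin_design(n = 100, nfac = 2)
  sc <- scan_p(d, p_grid = c(1.0, 0.8, 0.6), n_replicates = 300, seed = 6)
  tw <- sc$summaries$twist_pct  # descending P order
  n_alloc <- 100 * 300
  se <- sqrt(0.5 * 0.5 / n_alloc) * 100
  expect_true(all(diff(tw) > -3 * se))
})

test_that("with one factor, predictability barely moves as P drops to 0.7", {
  # with a single factor the extra twists are offset by the drop in ties,
  # so the deterministic percentage is nearly flat over P = 1.0 .. 0.7
  # (below that, ties genuinely thin out and predictability moves)
  d <- bin_design(n = 200, nfac = 1)
  sc <- scan_p(d, p_grid = c(1.0, 0.9, 0.8, 0.7), n_replicates = 400,
               seed = 10)
  det <- sc$summaries$deterministic_pct
  expect_lt(max(det) - min(det), 2)
})

test_that("scenario_grid runs a battery reproducibly", {
  designs <- list(a = bin_design(n = 40, nfac = 1),
                  b = bin_design(n = 40, nfac = 2))
  g1 <- scenario_grid(designs, p_grid = c(1.0, 0.7), n_replicates = 30, seed = 15)
  g2 <- scenario_grid(designs, p_grid = c(1.0, 0.7), n_replicates = 30, seed = 15)
  expect_equal(nrow(g1), 2)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_error(scenario_grid(list(), n_replicates = 10), "non-empty")
  expect_error(scenario_grid(designs, p_grid = numeric(0), n_replicates = 10),
               "non-empty")

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  render_report(g1, f1)
  render_report(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("the two-treatment battery enumerates the 13 factor configurations", {
  batt <- two_treatment_battery(100)
  expect_length(batt, 13)
  expect_true(all(vapply(batt, inherits, logical(1), "minim_design")))
  nvars <- vapply(batt, function(d) length(d$factors), integer(1))
  expect_equal(unname(table(nvars)), c(4L, 5L, 2L, 2L), ignore_attr = TRUE)
})
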