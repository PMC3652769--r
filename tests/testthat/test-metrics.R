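test_that("the small-trial cutoff schedule reproduces every tabulated row", {
  expect_equal(imbalance_cutoff(10), 40)
  expect_equal(imbalance_cutoff(20), 20)
  expect_equal(imbalance_cutoff(30), 10)
  expect_equal(imbalance_cutoff(40), 10)
  expect_equal(imbalance_cutoff(50), 5)
  # step behaviour between tabulated sizes, and far beyond
  expect_equal(imbalance_cutoff(c(1, 11, 21, 45, 49, 1000)),
               c(40, 20, 10, 10, 10, 5))
  expect_error(imbalance_cutoff(0), ">= 1")
})

test_that("overall imbalance is the max pairwise arm difference as % of N", {
  expect_equal(overall_imbalance_percent(c(27, 23), 50), 8)
  expect_equal(overall_imbalance_percent(c(25, 25), 50), 0)
  expect_equal(overall_imbalance_percent(c(20, 17, 13), 50), 14)

  # brute force over all arm pairs agrees, and relabelling is immaterial
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    totals <- as.integer(rmultinom(1, 60, rep(1, k)))
    brute <- max(outer(totals, totals, function(a, b) abs(a - b))) / 60 * 100
    expect_equal(overall_imbalance_percent(totals, 60), brute)
    expect_equal(overall_imbalance_percent(sample(totals), 60), brute)
  }
  expect_error(overall_imbalance_percent(c(10, 10), 50), "sum")
})

test_that("within-factor imbalance compares category proportions across arms", {
  # worked example, age band: 4/10 vs 1/10 in the >=80 category -> 30 points
  we <- load_worked_example()
  expect_equal(factor_imbalance_percent(we$table, 2), 30)

  # equal proportions in unequal arms -> 0
  d <- bin_design(n = 50, nfac = 1)
  tab <- marginal_table(d, counts = rbind(c(14L, 11L), c(14L, 11L)))
  expect_equal(factor_imbalance_percent(tab, 1), 0)

  # brute-force oracle over (category, arm-pair) combinations
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    arms <- sample(2:4, 1)
    counts <- matrix(rpois(k * arms, 5) + 1L, nrow = k)
    dd <- minim_design(arms, sum(counts), 1.0, factor_spec("f", rep(1 / k, k)))
    tt <- marginal_table(dd, counts = counts)
    prop <- sweep(counts, 2, colSums(counts), "/")
    brute <- 0
    for (cc in seq_len(k))
      for (a in seq_len(arms - 1))
        for (b in (a + 1):arms)
          brute <- max(brute, abs(prop[cc, a] - prop[cc, b]))
    expect_equal(factor_imbalance_percent(tt, 1), 100 * brute)
  }

  # empty arm: maximal imbalance with a warning
  tab0 <- marginal_table(d, counts = rbind(c(3L, 0L), c(2L, 0L)))
  expect_warning(v <- factor_imbalance_percent(tab0, 1), "empty")
  expect_equal(v, 100)
})

test_that("trial flags evaluate both statistics at the final-N cutoff", {
  # N = 50, arm totals (27, 23) with near-identical proportions:
  # overall flagged at the 5% cutoff, factors clean
  d <- bin_design(n = 50, nfac = 1)
  tab <- marginal_table(d, counts = rbind(c(14L, 12L), c(13L, 11L)))
  fl <- trial_flags(tab)
  expect_true(fl$overall_imbalanced)
  expect_false(fl$any_factor_imbalanced)
  expect_equal(fl$max_overall_percent, 8)
  expect_equal(fl$cutoff_percent, 5)

  # perfectly balanced table -> both flags false
  tab2 <- marginal_table(d, counts = rbind(c(13L, 13L), c(12L, 12L)))
  fl2 <- trial_flags(tab2)
  expect_false(fl2$overall_imbalanced)
  expect_false(fl2$any_factor_imbalanced)

  # flags recomputed from a replayed table equal flags from the final table
  dd <- minim_design(2, 40, 0.7, list(c(0.5, 0.5), c(0.5, 0.5)))
  tr <- run_trial(dd, seed = 3)
  expect_identical(trial_flags(tr), trial_flags(replay_records(tr)))
})

test_that("imbalance rule validates its threshold", {
  expect_error(imbalance_rule(chance_threshold = 0), "chance_threshold")
  expect_error(imbalance_rule(chance_threshold = 1), "chance_threshold")
  r <- imbalance_rule(chance_threshold = 0.2)
  expect_equal(r$chance_threshold, 0.2)
})

test_that("predictability is the deterministic fraction; ties and twists are unpredictable", {
  expect_equal(predictability_fraction(rep("tie", 5)), 0)
  expect_equal(predictability_fraction(c("tie", "deterministic", "twist",
                                         "deterministic")), 0.5)
  expect_error(predictability_fraction(character(0)), "undefined")

  # at P = 1 there are no twists, so predictability = 1 - tie fraction
  tr <- run_trial(bin_design(n = 100, p = 1.0, nfac = 2), seed = 12)
  cls <- tr$records$classification
  expect_equal(predictability_fraction(tr), 1 - mean(cls == "tie"))
  expect_equal(sum(cls == "twist"), 0)
})
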