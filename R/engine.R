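# Reproducibility contract: one master seed spawns one L'Ecuyer-CMRG child
# stream per replicate (stream id = replicate index), so replicates are
# order-independent; a sub-stream split separates cohort generation from
# allocation draws, letting a P-scan reuse each replicate's cohort across P
# values (common random numbers).

replicate_streams <- function(master_seed, n) {
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

with_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

tally_classifications <- function(cls_codes) {
  tabulate(cls_codes, nbins = 3L)
}

#' Simulate replicate trials and summarise one scenario
#'
#' Runs `n_replicates` independent trials of one design, pooling the
#' tie / deterministic / twist classification percentages over all
#' allocations and recording the fraction of replicates flagged for overall
#' or within-factor imbalance. The scenario's imbalance verdict is true when
#' either fraction reaches the rule's chance threshold (default: at least
#' 10% of replicates exceeding the size-dependent cutoff).
#'
#' @param design A [minim_design()].
#' @param n_replicates Number of replicate trials (default 1,000).
#' @param seed Master seed; each replicate gets its own RNG child stream.
#' @param rule An [imbalance_rule()].
#' @return An object of class `minim_scenario`: a one-row summary with
#'   `tie_pct`, `deterministic_pct`, `twist_pct`, `prob_overall_imbalance`,
#'   `prob_factor_imbalance` and `imbalance_verdict`.
#' @examples
#' d <- minim_design(2, 50, 1.0, factor_spec("biomarker", c(0.5, 0.5)))
#' run_replicates(d, n_replicates = 50, seed = 7)
#' @export
run_replicates <- function(design, n_replicates = 1000L, seed = 1L,
                           rule = imbalance_rule()) {
  stopifnot(inherits(design, "minim_design"))
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng_state(old), add = TRUE)

  streams <- replicate_streams(seed, n_replicates)
  tallies <- integer(3L)
  n_overall <- 0L
  n_factor <- 0L
  cutoff <- rule$cutoff_percent(design$n_patients)
  for (r in seq_len(n_replicates)) {
    with_rng_state(streams[[r]])
    cohort <- sample_cohort(design)
    with_rng_state(parallel::nextRNGSubStream(streams[[r]]))
    res <- run_trial_core(design, cohort, design$p_optimal,
                          keep_scores = FALSE)
    tallies <- tallies + tally_classifications(res$cls)
    fl <- flags_from_core(design, res, cutoff)
    n_overall <- n_overall + fl[1L]
    n_factor <- n_factor + fl[2L]
  }
  pct <- 100 * tallies / sum(tallies)
  p_overall <- n_overall / n_replicates
  p_factor <- n_factor / n_replicates
  structure(
    list(n_arms = design$n_arms, n_patients = design$n_patients,
         p_optimal = design$p_optimal,
         factor_fingerprint = design_fingerprint(design),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         tie_pct = pct[1L], deterministic_pct = pct[2L], twist_pct = pct[3L],
         prob_overall_imbalance = p_overall,
         prob_factor_imbalance = p_factor,
         imbalance_verdict = (p_overall >= rule$chance_threshold) ||
           (p_factor >= rule$chance_threshold)),
    class = "minim_scenario"
  )
}

# imbalance flags computed straight from the light-weight core result,
# avoiding marginal_table construction in the replicate loop
flags_from_core <- function(design, res, cutoff) {
  n <- design$n_patients
  overall <- 100 * (max(res$arm_totals) - min(res$arm_totals)) / n
  if (any(res$arm_totals == 0L)) {
    worst <- 100
  } else {
    worst <- 0
    for (f in seq_along(design$factors)) {
      block <- res$counts[row_indices(design, f), , drop = FALSE]
      prop <- block / rep(res$arm_totals, each = nrow(block))
      spread <- 100 * max(apply(prop, 1L, function(p) max(p) - min(p)))
      if (spread > worst) worst <- spread
    }
  }
  c(overall >= cutoff, worst >= cutoff)
}

design_fingerprint <- function(design) {
  paste(vapply(design$factors, function(f)
    paste0(length(f$prevalence), "cat(",
           paste(format(f$prevalence, trim = TRUE), collapse = "/"), ")"),
    character(1)), collapse = "+")
}

#' @export
print.minim_scenario <- function(x, ...) {
  cat("Scenario summary (", x$n_replicates, " replicates)\n", sep = "")
  cat("  arms =", x$n_arms, ", N =", x$n_patients,
      ", P =", format(x$p_optimal), ", factors:", x$factor_fingerprint, "\n")
  cat(sprintf("  tie / deterministic / twist: %.1f / %.1f / %.1f %%\n",
              x$tie_pct, x$deterministic_pct, x$twist_pct))
  cat(sprintf("  Pr(overall imbalance) = %.3f, Pr(factor imbalance) = %.3f -> %s\n",
              x$prob_overall_imbalance, x$prob_factor_imbalance,
              if (x$imbalance_verdict) "IMBALANCED" else "balanced"))
  invisible(x)
}

scenario_row <- function(s) {
  data.frame(n_arms = s$n_arms, n_patients = s$n_patients,
             p_optimal = s$p_optimal, factors = s$factor_fingerprint,
             n_replicates = s$n_replicates, seed = s$seed,
             tie_pct = s$tie_pct, deterministic_pct = s$deterministic_pct,
             twist_pct = s$twist_pct,
             prob_overall_imbalance = s$prob_overall_imbalance,
             prob_factor_imbalance = s$prob_factor_imbalance,
             imbalance_verdict = s$imbalance_verdict)
}

#' Scan the probability-of-optimal-allocation grid for one design
#'
#' Runs the replicate engine at each P of a grid (default 1.0 down to 0.5 in
#' steps of 0.1, the range from simple randomisation to fully deterministic
#' minimisation), sharing each replicate's cohort across P values. From the
#' per-P imbalance verdicts it derives:
#' \describe{
#'   \item{imbalance_onset_p}{the largest P at which the scenario is
#'     imbalanced (`NA` if never);}
#'   \item{recommended_p}{the smallest grid P above the onset with a clean
#'     verdict — the most random twist the design tolerates without
#'     compromising balance;}
#'   \item{predictability_reduction_pct}{deterministic percentage at the
#'     largest grid P minus that at the recommended P: the predictability
#'     bought by lowering P.}
#' }
#' If even the largest grid P is imbalanced, `recommended_p` is `NA` and the
#' result is flagged `no_balanced_p`.
#'
#' @param design A [minim_design()]; its own `p_optimal` is ignored, the grid
#'   is used instead.
#' @param p_grid Probabilities in \[0.5, 1\], scanned in descending order.
#' @inheritParams run_replicates
#' @return An object of class `minim_pscan`: per-P summary data frame plus
#'   the derived recommendation fields.
#' @examples
#' d <- minim_design(2, 50, 1.0, list(c(0.5, 0.5), c(0.5, 0.5)))
#' scan_p(d, n_replicates = 50, seed = 7)
#' @export
scan_p <- function(design, p_grid = seq(1.0, 0.5, by = -0.1),
                   n_replicates = 1000L, seed = 1L, rule = imbalance_rule()) {
  stopifnot(inherits(design, "minim_design"))
  if (length(p_grid) == 0L) stop("'p_grid' must be non-empty", call. = FALSE)
  if (any(p_grid < 0.5 | p_grid > 1))
    stop("'p_grid' values must lie in [0.5, 1]", call. = FALSE)
  p_grid <- sort(unique(as.numeric(p_grid)), decreasing = TRUE)
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng_state(old), add = TRUE)

  streams <- replicate_streams(seed, n_replicates)
  np <- length(p_grid)
  tallies <- matrix(0L, nrow = np, ncol = 3L)
  n_overall <- integer(np)
  n_factor <- integer(np)
  cutoff <- rule$cutoff_percent(design$n_patients)
  for (r in seq_len(n_replicates)) {
    with_rng_state(streams[[r]])
    cohort <- sample_cohort(design)
    alloc_state <- parallel::nextRNGSubStream(streams[[r]])
    for (k in seq_len(np)) {
      with_rng_state(alloc_state)
      res <- run_trial_core(design, cohort, p_grid[k], keep_scores = FALSE)
      tallies[k, ] <- tallies[k, ] + tally_classifications(res$cls)
      fl <- flags_from_core(design, res, cutoff)
      n_overall[k] <- n_overall[k] + fl[1L]
      n_factor[k] <- n_factor[k] + fl[2L]
    }
  }
  total <- design$n_patients * n_replicates
  p_overall <- n_overall / n_replicates
  p_factor <- n_factor / n_replicates
  summaries <- data.frame(
    n_arms = design$n_arms, n_patients = design$n_patients,
    p_optimal = p_grid, factors = design_fingerprint(design),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    tie_pct = 100 * tallies[, 1L] / total,
    deterministic_pct = 100 * tallies[, 2L] / total,
    twist_pct = 100 * tallies[, 3L] / total,
    prob_overall_imbalance = p_overall,
    prob_factor_imbalance = p_factor,
    imbalance_verdict = (p_overall >= rule$chance_threshold) |
      (p_factor >= rule$chance_threshold)
  )
  rec <- recommend_p(summaries)
  structure(
    c(list(summaries = summaries, design = design,
           n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
      rec),
    class = "minim_pscan"
  )
}

# Recommendation rule over a descending-P summary table. With verdicts
# monotone in P (the usual regime) the recommended P is simply the smallest
# balanced grid value; requiring it to sit above the onset keeps the rule
# well defined if Monte-Carlo noise makes verdicts non-monotone.
recommend_p <- function(summaries) {
  p <- summaries$p_optimal
  bad <- summaries$imbalance_verdict
  onset <- if (any(bad)) max(p[bad]) else NA_real_
  candidates <- if (is.na(onset)) p[!bad] else p[!bad & p > onset]
  if (length(candidates) == 0L) {
    return(list(recommended_p = NA_real_, imbalance_onset_p = onset,
                predictability_reduction_pct = NA_real_,
                no_balanced_p = TRUE))
  }
  rec <- min(candidates)
  det_top <- summaries$deterministic_pct[which.max(p)]
  det_rec <- summaries$deterministic_pct[p == rec][1L]
  list(recommended_p = rec, imbalance_onset_p = onset,
       predictability_reduction_pct = det_top - det_rec,
       no_balanced_p = FALSE)
}

#' @export
print.minim_pscan <- function(x, digits = 1, ...) {
  d <- x$design
  cat("P-scan:", d$n_arms, "arms, N =", d$n_patients,
      ", factors:", design_fingerprint(d),
      paste0("(", x$n_replicates, " replicates)\n"))
  s <- x$summaries
  out <- data.frame(P = s$p_optimal,
                    tie = round(s$tie_pct, digits),
                    deterministic = round(s$deterministic_pct, digits),
                    twist = round(s$twist_pct, digits),
                    pr_overall = round(s$prob_overall_imbalance, 3),
                    pr_factor = round(s$prob_factor_imbalance, 3),
                    imbalanced = s$imbalance_verdict)
  print(out, row.names = FALSE)
  if (isTRUE(x$no_balanced_p)) {
    cat("No balanced P in grid.\n")
  } else {
    cat(sprintf("Recommended P = %.1f (imbalance onset: %s), predictability reduction %.1f%%\n",
                x$recommended_p,
                if (is.na(x$imbalance_onset_p)) "-" else
                  sprintf("%.1f", x$imbalance_onset_p),
                x$predictability_reduction_pct))
  }
  invisible(x)
}

#' @export
plot.minim_pscan <- function(x, ...) {
  s <- x$summaries
  op <- graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(graphics::par(op), add = TRUE)
  plot(s$p_optimal, s$deterministic_pct, type = "b", pch = 19,
       xlim = rev(range(s$p_optimal)), ylim = c(0, 100),
       xlab = "Probability of optimal allocation P",
       ylab = "Deterministic allocations (%)", ...)
  graphics::par(new = TRUE)
  plot(s$p_optimal, pmax(s$prob_overall_imbalance, s$prob_factor_imbalance),
       type = "b", pch = 1, lty = 2, col = "red3", axes = FALSE,
       xlab = "", ylab = "", xlim = rev(range(s$p_optimal)), ylim = c(0, 1))
  graphics::axis(4, col.axis = "red3")
  graphics::mtext("Pr(imbalance)", side = 4, line = 3, col = "red3")
  graphics::abline(h = 0.10, col = "red3", lty = 3)
  if (!is.na(x$recommended_p))
    graphics::abline(v = x$recommended_p, col = "grey40", lty = 3)
  invisible(x)
}

#' Run a battery of designs over the P grid
#'
#' One [scan_p()] per design, with a distinct deterministic seed per design
#' derived from the master seed. Returns one row per design in the style of
#' the summary tables: predictability at the top of the grid, recommended P,
#' predictability there, the reduction, and the imbalance-onset P.
#'
#' @param designs Named list of [minim_design()] objects (their `p_optimal`
#'   fields are ignored).
#' @inheritParams scan_p
#' @return An object of class `minim_grid`: a data frame (one row per
#'   design), with the full list of `minim_pscan` objects in attribute
#'   `"scans"`.
#' @export
scenario_grid <- function(designs, p_grid = seq(1.0, 0.5, by = -0.1),
                          n_replicates = 1000L, seed = 1L,
                          rule = imbalance_rule()) {
  if (!is.list(designs) || length(designs) == 0L ||
      !all(vapply(designs, inherits, logical(1), "minim_design")))
    stop("'designs' must be a non-empty list of minim_design objects",
         call. = FALSE)
  if (length(p_grid) == 0L) stop("'p_grid' must be non-empty", call. = FALSE)
  labels <- names(designs)
  if (is.null(labels)) labels <- paste0("design", seq_along(designs))
  scans <- vector("list", length(designs))
  rows <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    design_seed <- as.integer((as.numeric(seed) + (i - 1) * 10007) %%
                                .Machine$integer.max)
    sc <- scan_p(designs[[i]], p_grid = p_grid, n_replicates = n_replicates,
                 seed = design_seed, rule = rule)
    scans[[i]] <- sc
    s <- sc$summaries
    top <- which.max(s$p_optimal)
    rows[[i]] <- data.frame(
      label = labels[i],
      n_arms = designs[[i]]$n_arms,
      n_patients = designs[[i]]$n_patients,
      factors = design_fingerprint(designs[[i]]),
      predictability_at_pmax = s$deterministic_pct[top],
      recommended_p = sc$recommended_p,
      predictability_at_recommended =
        if (is.na(sc$recommended_p)) NA_real_ else
          s$deterministic_pct[s$p_optimal == sc$recommended_p][1L],
      reduction_pct = sc$predictability_reduction_pct,
      imbalance_onset_p = sc$imbalance_onset_p,
      n_replicates = as.integer(n_replicates),
      seed = design_seed)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, scans = stats::setNames(scans, labels),
            class = c("minim_grid", "data.frame"))
}

#' The two-treatment design battery
#'
#' The thirteen factor configurations explored in the two-treatment case:
#' one variable with 2 (equal and unequal prevalence), 3 or 4 categories;
#' two variables (2+2 equal and unequal, 2+3, 3+3, 4+4); three and four
#' binary variables (equal and unequal). Unequal prevalences use
#' [prevalence_preset()].
#'
#' @param n_patients Trial size for every design.
#' @return Named list of [minim_design()] objects (with `p_optimal = 1`,
#'   which [scenario_grid()] ignores).
#' @export
two_treatment_battery <- function(n_patients = 200L) {
  eq <- function(k) prevalence_preset(k, "equal")
  uneq <- function(k) prevalence_preset(k, "unequal")
  mk <- function(...) minim_design(2L, n_patients, 1.0, list(...))
  list(
    "1var_2cat"          = mk(eq(2)),
    "1var_2cat_unequal"  = mk(uneq(2)),
    "1var_3cat"          = mk(eq(3)),
    "1var_4cat"          = mk(eq(4)),
    "2var_2cat"          = mk(eq(2), eq(2)),
    "2var_2cat_unequal"  = mk(uneq(2), uneq(2)),
    "2var_2cat_3cat"     = mk(eq(2), eq(3)),
    "2var_3cat"          = mk(eq(3), eq(3)),
    "2var_4cat"          = mk(eq(4), eq(4)),
    "3var_2cat"          = mk(eq(2), eq(2), eq(2)),
    "3var_2cat_unequal"  = mk(uneq(2), uneq(2), uneq(2)),
    "4var_2cat"          = mk(eq(2), eq(2), eq(2), eq(2)),
    "4var_2cat_unequal"  = mk(uneq(2), uneq(2), uneq(2), uneq(2))
  )
}
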