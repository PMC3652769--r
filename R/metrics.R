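#' Imbalance cutoff schedule
#'
#' Threshold (in percent of N) beyond which a treatment-arm or within-factor
#' difference counts as imbalance. For trials of at least 50 patients the
#' cutoff is a 5% absolute imbalance; for very small trials 5% of N is a
#' negligible head-count, so the cutoff is raised on a step schedule:
#' N <= 10 -> 40%, 11-20 -> 20%, 21-49 -> 10%, N >= 50 -> 5%. The schedule
#' is tabulated only at N = 10, 20, 30, 40 and >= 50; each gap takes the
#' cutoff of the next tabulated size, and 41-49 extends the N = 40 value.
#'
#' @param n_patients Trial size N (vectorised), >= 1.
#' @return Percentage cutoff(s).
#' @examples
#' imbalance_cutoff(c(10, 20, 30, 40, 50, 1000))
#' @export
imbalance_cutoff <- function(n_patients) {
  if (any(n_patients < 1)) stop("'n_patients' must be >= 1", call. = FALSE)
  ifelse(n_patients <= 10, 40,
         ifelse(n_patients <= 20, 20,
                ifelse(n_patients <= 49, 10, 5)))
}

#' Imbalance rule
#'
#' Bundles the size-dependent cutoff schedule with the chance threshold used
#' at scenario level: a design cell is declared imbalanced when at least
#' `chance_threshold` (default 10%) of replicate trials exceed the cutoff.
#'
#' @param cutoff_percent Function of N returning a percentage cutoff;
#'   defaults to [imbalance_cutoff()]. Must be non-increasing in N.
#' @param chance_threshold Probability in (0, 1); default 0.10.
#' @return An object of class `imbalance_rule`.
#' @export
imbalance_rule <- function(cutoff_percent = imbalance_cutoff,
                           chance_threshold = 0.10) {
  stopifnot(is.function(cutoff_percent))
  if (chance_threshold <= 0 || chance_threshold >= 1)
    stop("'chance_threshold' must lie in (0, 1)", call. = FALSE)
  structure(list(cutoff_percent = cutoff_percent,
                 chance_threshold = chance_threshold),
            class = "imbalance_rule")
}

#' Overall treatment imbalance
#'
#' The largest pairwise difference in arm sizes, as a percentage of the trial
#' size N. With two arms this is `100 * |nA - nB| / N`; with more arms the
#' maximum over arm pairs is taken.
#'
#' @param arm_totals Integer vector of patients per arm.
#' @param n_patients Trial size; must equal `sum(arm_totals)`.
#' @return Percentage imbalance.
#' @examples
#' overall_imbalance_percent(c(27, 23), 50)  # 8: the minimal flagged split
#' @export
overall_imbalance_percent <- function(arm_totals, n_patients) {
  if (sum(arm_totals) != n_patients)
    stop("arm totals sum to ", sum(arm_totals), ", not n_patients = ",
         n_patients, call. = FALSE)
  if (n_patients < 1) stop("'n_patients' must be >= 1", call. = FALSE)
  100 * (max(arm_totals) - min(arm_totals)) / n_patients
}

#' Within-factor treatment imbalance
#'
#' For one prognostic factor, the largest percentage-point difference between
#' any two arms in the proportion of their patients carrying any one
#' category. Proportions (not raw counts) are compared so that the statistic
#' is meaningful for arms of unequal size.
#'
#' If any arm is still empty the proportions are undefined; the factor is
#' then reported as maximally imbalanced (100) with a warning. This only
#' arises for tiny trials.
#'
#' @param table A [marginal_table()].
#' @param factor_index 1-based index of the factor in the design.
#' @return Percentage-point imbalance.
#' @export
factor_imbalance_percent <- function(table, factor_index) {
  stopifnot(inherits(table, "marginal_table"))
  d <- table$design
  if (factor_index < 1L || factor_index > length(d$factors))
    stop("'factor_index' out of range", call. = FALSE)
  if (any(table$arm_totals == 0L)) {
    warning("empty treatment arm: factor imbalance reported as maximal (100)")
    return(100)
  }
  block <- table$counts[row_indices(d, factor_index), , drop = FALSE]
  prop <- sweep(block, 2L, table$arm_totals, "/")
  # max over categories of the arm-pair proportion spread
  100 * max(apply(prop, 1L, function(p) max(p) - min(p)))
}

#' Evaluate a finished trial against the imbalance rule
#'
#' Computes the overall arm-size imbalance and the worst within-factor
#' imbalance at the final N, and flags each against the size-dependent
#' cutoff.
#'
#' @param trial A [run_trial()] result (or a [marginal_table()] of a
#'   completed trial).
#' @param rule An [imbalance_rule()].
#' @return A list of class `trial_flags` with `overall_imbalanced`,
#'   `any_factor_imbalanced`, `max_overall_percent`, `max_factor_percent` and
#'   `cutoff_percent`.
#' @export
trial_flags <- function(trial, rule = imbalance_rule()) {
  tab <- if (inherits(trial, "minim_trial")) trial$final_table else trial
  stopifnot(inherits(tab, "marginal_table"), inherits(rule, "imbalance_rule"))
  n <- tab$n_allocated
  cutoff <- rule$cutoff_percent(n)
  overall <- overall_imbalance_percent(tab$arm_totals, n)
  per_factor <- vapply(seq_along(tab$design$factors),
                       function(f) factor_imbalance_percent(tab, f),
                       numeric(1))
  structure(
    list(overall_imbalanced = overall >= cutoff,
         any_factor_imbalanced = max(per_factor) >= cutoff,
         max_overall_percent = overall,
         max_factor_percent = max(per_factor),
         cutoff_percent = cutoff),
    class = "trial_flags"
  )
}

#' Allocation predictability
#'
#' The fraction of allocations an observer could have called with certainty,
#' knowing the algorithm and every prior allocation: exactly those classified
#' deterministic. Ties (resolved by simple randomisation) and random twists
#' are unpredictable.
#'
#' @param records A `minim_trial` records data frame, a [run_trial()] result,
#'   or a classification factor/character vector.
#' @return Fraction in \[0, 1\].
#' @export
predictability_fraction <- function(records) {
  if (inherits(records, "minim_trial")) records <- records$records
  cls <- if (is.data.frame(records)) records$classification else records
  if (length(cls) == 0L)
    stop("no allocation records: predictability is undefined", call. = FALSE)
  mean(cls == "deterministic")
}
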