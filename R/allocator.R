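#' Create an empty marginal table
#'
#' The allocator's state: for every (factor, category, arm) the number of
#' previously allocated patients, plus per-arm totals. Counts are stored as a
#' matrix with one row per flattened (factor, category) cell and one column
#' per arm.
#'
#' @param design A [minim_design()].
#' @param counts Optional pre-filled counts matrix (rows = total categories
#'   across factors, columns = arms), used when restoring a mid-trial state
#'   such as the packaged worked example.
#' @return An object of class `marginal_table`.
#' @export
marginal_table <- function(design, counts = NULL) {
  stopifnot(inherits(design, "minim_design"))
  n_rows <- sum(design$n_categories)
  if (is.null(counts)) {
    counts <- matrix(0L, nrow = n_rows, ncol = design$n_arms)
  } else {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (nrow(counts) != n_rows || ncol(counts) != design$n_arms)
      stop("'counts' must be ", n_rows, " x ", design$n_arms, call. = FALSE)
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  }
  rownames(counts) <- unlist(lapply(design$factors, function(f)
    paste(f$name, f$labels, sep = ":")))
  tab <- structure(
    list(design = design, counts = counts,
         arm_totals = integer(design$n_arms), n_allocated = 0L),
    class = "marginal_table"
  )
  # arm totals are recoverable from any single factor's column sums
  tab$arm_totals <- as.integer(colSums(counts[row_indices(design, 1L), ,
                                              drop = FALSE]))
  tab$n_allocated <- sum(tab$arm_totals)
  validate_marginal_table(tab)
  tab
}

row_indices <- function(design, f) {
  design$row_offset[f] + seq_len(design$n_categories[f])
}

validate_marginal_table <- function(tab) {
  d <- tab$design
  for (f in seq_along(d$factors)) {
    block <- tab$counts[row_indices(d, f), , drop = FALSE]
    if (sum(block) != tab$n_allocated)
      stop("marginal table inconsistent: factor '", d$factors[[f]]$name,
           "' counts sum to ", sum(block), ", not n_allocated = ",
           tab$n_allocated, call. = FALSE)
    if (!all(colSums(block) == tab$arm_totals))
      stop("marginal table inconsistent: factor '", d$factors[[f]]$name,
           "' column sums disagree with arm totals", call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.marginal_table <- function(x, ...) {
  cat("Marginal table:", x$n_allocated, "patients over", x$design$n_arms,
      "arms (totals:", paste(x$arm_totals, collapse = ", "), ")\n")
  m <- x$counts
  colnames(m) <- paste0("arm", seq_len(ncol(m)))
  print(m)
  invisible(x)
}

#' Marginal minimisation scores
#'
#' For each arm, the sum over prognostic factors of the count of previously
#' allocated patients sharing the incoming patient's category of that factor.
#' The arm with the unique smallest score is the optimal treatment.
#'
#' @param table A [marginal_table()].
#' @param patient Integer vector of 1-based category indices, one per factor.
#' @return Integer vector of per-arm scores.
#' @examples
#' we <- load_worked_example()
#' marginal_scores(we$table, we$patient)  # 18 27
#' @export
marginal_scores <- function(table, patient) {
  stopifnot(inherits(table, "marginal_table"))
  d <- table$design
  patient <- as.integer(patient)
  if (length(patient) != length(d$factors))
    stop("patient has ", length(patient), " levels; design has ",
         length(d$factors), " factors", call. = FALSE)
  if (any(patient < 1L | patient > d$n_categories))
    stop("patient level out of range for its factor", call. = FALSE)
  rows <- d$row_offset + patient
  sc <- table$counts[rows[1L], ]
  for (r in rows[-1L]) sc <- sc + table$counts[r, ]
  as.integer(sc)
}

#' Allocate one patient by minimisation with a random twist
#'
#' Computes the patient's marginal scores, then: if the minimum score is
#' shared by two or more arms, assigns by simple randomisation among the tied
#' arms (classification `"tie"`); otherwise assigns the unique minimiser with
#' probability `p_optimal` (`"deterministic"`), and with probability
#' `1 - p_optimal` assigns uniformly among the remaining arms (`"twist"`).
#' The table is updated only after the decision: the patient never
#' contributes to their own scores.
#'
#' @inheritParams marginal_scores
#' @param p_optimal Probability of allocating the optimal arm; defaults to
#'   the design's value.
#' @return A list with components `arm` (assigned arm index), `classification`
#'   (`"tie"`, `"deterministic"` or `"twist"`), `scores` (per-arm scores at
#'   decision time) and `table` (the updated [marginal_table()]).
#' @examples
#' we <- load_worked_example()
#' allocate(we$table, we$patient, p_optimal = 1.0)[c("arm", "classification")]
#' @export
allocate <- function(table, patient, p_optimal = table$design$p_optimal) {
  stopifnot(inherits(table, "marginal_table"))
  if (p_optimal < 0.5 || p_optimal > 1)
    stop("'p_optimal' must lie in [0.5, 1]", call. = FALSE)
  d <- table$design
  sc <- marginal_scores(table, patient)
  tied <- which(sc == min(sc))
  if (length(tied) > 1L) {
    arm <- tied[sample.int(length(tied), 1L)]
    cls <- "tie"
  } else if (stats::runif(1L) <= p_optimal) {
    arm <- tied
    cls <- "deterministic"
  } else {
    others <- seq_len(d$n_arms)[-tied]
    arm <- others[sample.int(d$n_arms - 1L, 1L)]
    cls <- "twist"
  }
  rows <- d$row_offset + as.integer(patient)
  table$counts[rows, arm] <- table$counts[rows, arm] + 1L
  table$arm_totals[arm] <- table$arm_totals[arm] + 1L
  table$n_allocated <- table$n_allocated + 1L
  list(arm = arm, classification = cls, scores = sc, table = table)
}

# Tight inner loop shared by run_trial() and the replicate engine.
# levels_mat: N x F matrix of 1-based category indices.
# Returns arm / classification codes (1 tie, 2 deterministic, 3 twist),
# per-decision scores, final counts and arm totals.
run_trial_core <- function(design, levels_mat, p_optimal, keep_scores = TRUE) {
  n <- nrow(levels_mat)
  n_arms <- design$n_arms
  offs <- design$row_offset
  counts <- matrix(0L, nrow = sum(design$n_categories), ncol = n_arms)
  arm_totals <- integer(n_arms)
  arm <- integer(n)
  cls <- integer(n)
  scores <- if (keep_scores) matrix(0L, nrow = n, ncol = n_arms) else NULL
  for (i in seq_len(n)) {
    rows <- offs + levels_mat[i, ]
    sc <- counts[rows[1L], ]
    for (r in rows[-1L]) sc <- sc + counts[r, ]
    mn <- min(sc)
    tied <- which(sc == mn)
    if (length(tied) > 1L) {
      a <- tied[sample.int(length(tied), 1L)]
      k <- 1L
    } else if (stats::runif(1L) <= p_optimal) {
      a <- tied
      k <- 2L
    } else {
      others <- seq_len(n_arms)[-tied]
      a <- others[sample.int(n_arms - 1L, 1L)]
      k <- 3L
    }
    counts[rows, a] <- counts[rows, a] + 1L
    arm_totals[a] <- arm_totals[a] + 1L
    arm[i] <- a
    cls[i] <- k
    if (keep_scores) scores[i, ] <- sc
  }
  list(arm = arm, cls = cls, scores = scores, counts = counts,
       arm_totals = arm_totals)
}

CLASSIFICATION_LEVELS <- c("tie", "deterministic", "twist")

#' Run one minimisation trial
#'
#' Sequentially allocates a cohort of patients starting from an empty
#' marginal table, recording for every allocation the assigned arm, the
#' per-arm scores at decision time and the classification (tie /
#' deterministic / twist).
#'
#' @param design A [minim_design()].
#' @param cohort Integer matrix of patient levels (rows = patients, columns =
#'   factors, 1-based category indices), e.g. from [sample_cohort()]. If
#'   `NULL`, a cohort is sampled from the design's prevalences. Must have
#'   exactly `design$n_patients` rows.
#' @param seed Optional integer seed applied with [set.seed()] before any
#'   draws, for a self-contained reproducible run.
#' @return An object of class `minim_trial`: a list with `design`, `cohort`,
#'   `records` (data frame: entry order, factor levels, per-arm scores,
#'   assigned arm, classification) and `final_table` (a [marginal_table()]).
#' @examples
#' d <- minim_design(2, 40, 1.0, list(c(0.5, 0.5), c(0.5, 0.5)))
#' tr <- run_trial(d, seed = 42)
#' summary(tr)
#' @export
run_trial <- function(design, cohort = NULL, seed = NULL) {
  stopifnot(inherits(design, "minim_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cohort)) cohort <- sample_cohort(design)
  cohort <- as.matrix(cohort)
  storage.mode(cohort) <- "integer"
  if (nrow(cohort) != design$n_patients)
    stop("cohort has ", nrow(cohort), " patients; design expects ",
         design$n_patients, call. = FALSE)
  if (ncol(cohort) != length(design$factors))
    stop("cohort has ", ncol(cohort), " columns; design has ",
         length(design$factors), " factors", call. = FALSE)
  if (any(cohort < 1L) || any(cohort > rep(design$n_categories,
                                           each = nrow(cohort))))
    stop("cohort contains out-of-range category indices", call. = FALSE)

  res <- run_trial_core(design, cohort, design$p_optimal, keep_scores = TRUE)

  scores <- res$scores
  colnames(scores) <- paste0("score_arm", seq_len(design$n_arms))
  lv <- cohort
  colnames(lv) <- paste0("level_", vapply(design$factors, `[[`, character(1),
                                          "name"))
  records <- data.frame(entry_order = seq_len(nrow(cohort)), lv, scores,
                        arm = res$arm,
                        classification = factor(
                          CLASSIFICATION_LEVELS[res$cls],
                          levels = CLASSIFICATION_LEVELS),
                        row.names = NULL)
  final <- marginal_table(design, counts = res$counts)
  structure(
    list(design = design, cohort = cohort, records = records,
         final_table = final),
    class = "minim_trial"
  )
}

#' @export
print.minim_trial <- function(x, ...) {
  cat("Minimisation trial:", nrow(x$records), "patients,",
      x$design$n_arms, "arms, P =", format(x$design$p_optimal), "\n")
  cat("  arm totals:", paste(x$final_table$arm_totals, collapse = ", "), "\n")
  tab <- table(x$records$classification)
  cat("  classifications:",
      paste(names(tab), as.integer(tab), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.minim_trial <- function(object, rule = imbalance_rule(), ...) {
  cls <- object$records$classification
  n <- length(cls)
  flags <- trial_flags(object, rule = rule)
  out <- list(
    n_patients = n,
    n_arms = object$design$n_arms,
    p_optimal = object$design$p_optimal,
    arm_totals = object$final_table$arm_totals,
    classification_pct = 100 * as.vector(table(cls)) / n,
    predictability = predictability_fraction(object$records),
    flags = flags
  )
  names(out$classification_pct) <- CLASSIFICATION_LEVELS
  class(out) <- "summary.minim_trial"
  out
}

#' @export
print.summary.minim_trial <- function(x, ...) {
  cat("Minimisation trial summary\n")
  cat("  N =", x$n_patients, ", arms =", x$n_arms,
      ", P =", format(x$p_optimal), "\n")
  cat("  arm totals:", paste(x$arm_totals, collapse = ", "), "\n")
  cat("  tie / deterministic / twist (%):",
      paste(format(x$classification_pct, digits = 3), collapse = " / "), "\n")
  cat("  predictability:", format(100 * x$predictability, digits = 3), "%\n")
  cat("  overall imbalance:", format(x$flags$max_overall_percent, digits = 3),
      "% (cutoff", x$flags$cutoff_percent, "%) ->",
      if (x$flags$overall_imbalanced) "IMBALANCED" else "balanced", "\n")
  cat("  worst factor imbalance:",
      format(x$flags$max_factor_percent, digits = 3), "% ->",
      if (x$flags$any_factor_imbalanced) "IMBALANCED" else "balanced", "\n")
  invisible(x)
}

#' Replay a trial's allocation records
#'
#' Rebuilds the marginal table by replaying the recorded (patient, arm)
#' sequence from an empty table. Used to verify that a trial's `final_table`
#' is consistent with its records.
#'
#' @param trial A [run_trial()] result.
#' @return A [marginal_table()].
#' @export
replay_records <- function(trial) {
  stopifnot(inherits(trial, "minim_trial"))
  d <- trial$design
  counts <- matrix(0L, nrow = sum(d$n_categories), ncol = d$n_arms)
  for (i in seq_len(nrow(trial$cohort))) {
    rows <- d$row_offset + trial$cohort[i, ]
    a <- trial$records$arm[i]
    counts[rows, a] <- counts[rows, a] + 1L
  }
  marginal_table(d, counts = counts)
}

#' Simulate replicate trials from a design
#'
#' `simulate()` on a [minim_design()] draws `nsim` independent trials, each
#' with a fresh cohort, using one RNG child stream per replicate so results
#' do not depend on execution order.
#'
#' @param object A [minim_design()].
#' @param nsim Number of replicate trials.
#' @param seed Master seed for the replicate streams.
#' @param ... Unused.
#' @return A list of [run_trial()] results, of class `minim_trial_list`.
#' @export
simulate.minim_design <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  streams <- replicate_streams(seed, nsim)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    with_rng_state(streams[[r]])
    out[[r]] <- run_trial(object)
  }
  structure(out, class = "minim_trial_list", seed = seed)
}
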