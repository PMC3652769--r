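# Exhaustive dynamic-programming oracle for small designs: exact
# probabilities of each classification (tie / deterministic / twist) at each
# entry step, marginalising over all cohorts and all random choices
# (tie-break uniform among tied arms; optimal arm w.p. P; twist uniform
# among the non-optimal arms). Independent of the package's allocation loop:
# it enumerates marginal-count states directly.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_step_probs <- function(design, p_optimal = design$p_optimal) {
  d <- design
  n_arms <- d$n_arms
  n_rows <- sum(d$n_categories)
  types <- as.matrix(expand.grid(lapply(d$factors, function(f)
    seq_along(f$prevalence))))
  type_prob <- apply(as.matrix(expand.grid(lapply(d$factors, function(f)
    f$prevalence))), 1L, prod)
  key <- function(counts) paste(counts, collapse = ",")

  states <- new.env(parent = emptyenv())
  assign(key(integer(n_rows * n_arms)), 1, envir = states)
  out <- matrix(0, nrow = d$n_patients, ncol = 3L,
                dimnames = list(NULL, c("tie", "deterministic", "twist")))

  for (step in seq_len(d$n_patients)) {
    nxt <- new.env(parent = emptyenv())
    add <- function(cnt, pr) {
      k <- key(cnt)
      assign(k, pr + (get0(k, envir = nxt) %||% 0), envir = nxt)
    }
    for (k in ls(states)) {
      pr_state <- get(k, envir = states)
      counts <- matrix(as.integer(strsplit(k, ",", fixed = TRUE)[[1]]),
                       nrow = n_rows, ncol = n_arms)
      for (ti in seq_len(nrow(types))) {
        pt <- type_prob[ti]
        rows <- d$row_offset + types[ti, ]
        sc <- colSums(counts[rows, , drop = FALSE])
        tied <- which(sc == min(sc))
        if (length(tied) > 1L) {
          out[step, 1L] <- out[step, 1L] + pr_state * pt
          for (a in tied) {
            c2 <- counts
            c2[rows, a] <- c2[rows, a] + 1L
            add(c2, pr_state * pt / length(tied))
          }
        } else {
          out[step, 2L] <- out[step, 2L] + pr_state * pt * p_optimal
          c2 <- counts
          c2[rows, tied] <- c2[rows, tied] + 1L
          add(c2, pr_state * pt * p_optimal)
          if (p_optimal < 1) {
            out[step, 3L] <- out[step, 3L] + pr_state * pt * (1 - p_optimal)
            for (a in setdiff(seq_len(n_arms), tied)) {
              c2 <- counts
              c2[rows, a] <- c2[rows, a] + 1L
              add(c2, pr_state * pt * (1 - p_optimal) / (n_arms - 1L))
            }
          }
        }
      }
    }
    states <- nxt
  }
  out
}

# Monte-Carlo per-step classification frequencies over independent replicate
# trials of one design.
mc_step_freqs <- function(design, n_reps, seed) {
  n <- design$n_patients
  tal <- matrix(0L, nrow = n, ncol = 3L)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cohort <- sample_cohort(design)
    res <- minimsim:::run_trial_core(design, cohort, design$p_optimal,
                                     keep_scores = FALSE)
    idx <- cbind(seq_len(n), res$cls)
    tal[idx] <- tal[idx] + 1L
  }
  tal / n_reps
}

# compare every (step, classification) Monte-Carlo frequency to the oracle
# probability within the exact binomial 99% interval
expect_mc_matches_oracle <- function(design, n_reps, seed) {
  ex <- oracle_step_probs(design)
  ob <- mc_step_freqs(design, n_reps, seed)
  for (step in seq_len(nrow(ex))) {
    for (kk in 1:3) {
      ci <- binom_ci99(ex[step, kk], n_reps)
      expect_gte(ob[step, kk], ci[1])
      expect_lte(ob[step, kk], ci[2])
    }
  }
  invisible(NULL)
}
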