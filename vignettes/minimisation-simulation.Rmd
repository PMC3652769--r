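---
title: "Minimisation, predictability and baseline imbalance: the methods behind minimsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimisation, predictability and baseline imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimsim)
```

## The allocation model

minimsim implements marginal-total minimisation (the Pocock–Simon scheme) for
allocating patients to the arms of a randomised clinical trial so that the
arms stay balanced on a set of prognostic factors. The allocator's state is
the *marginal table*: for every factor $f$, category $c$ and arm $a$, the
count $n_{fca}$ of previously allocated patients. When a patient with
categories $c_1, \dots, c_F$ arrives, each arm receives the *marginal score*

$$ S_a \;=\; \sum_{f=1}^{F} n_{f c_f a}, $$

the number of already-allocated patients who share the incoming patient's
category, summed over factors (raw counts, unweighted — there is no
range/variance refinement and no factor weighting). The arm with the
smallest score is the *optimal treatment*. The decision rule is:

1. **Tie** — if the minimum of $S_a$ is attained by $m \ge 2$ arms, the
   patient is allocated by simple randomisation among those $m$ tied arms
   (probability $1/m$ each).
2. **Deterministic** — otherwise the unique minimiser is assigned with
   probability $P$.
3. **Random twist** — with the remaining probability $1 - P$ the patient
   goes to one of the other $A - 1$ arms, chosen uniformly.

The table is updated only *after* the decision: a patient never contributes
to their own scores. $P$ ranges over $[0.5, 1]$: $P = 1$ is fully
deterministic minimisation, and $P = 0.5$ with two arms degenerates to
simple randomisation whenever the minimiser is unique.

Two conventions in steps 1 and 3 are genuinely open for more than two arms,
where the two-arm description does not pin them down. We resolve them as
follows and treat the choices as part of the package's definition of the
algorithm:

* ties are randomised **among the tied-for-minimum arms only**, not among
  all arms — the standard Pocock–Simon reading, and identical to the
  alternative in the two-arm case;
* the twist probability $1 - P$ is split **uniformly over all non-optimal
  arms**, regardless of their score ranking, which keeps $P$ exactly the
  probability of the optimal arm.

## Predictability

An observer who knows the algorithm, the factor values and the allocations
of every previous patient can compute the scores of the incoming patient.
The allocation is *predictable with certainty* exactly when it is classified
deterministic: a unique minimiser existed and the patient went there. Ties
(resolved by a fair draw) and twists are not predictable, even though a
guesser would still be right some of the time (about half the time in a
two-arm tie). **Predictability** of a scenario is the percentage of
allocations classified deterministic, pooled over all allocations of all
replicate trials (with $N$ fixed this equals the mean per-trial fraction).
This is a certainty criterion, not a guessing strategy: heuristics based on
the previous allocation(s) are a different — and out of scope — notion.

## Imbalance

Two statistics are computed at the end of each simulated trial:

* **overall treatment imbalance** — the largest pairwise difference in arm
  sizes as a percentage of $N$, $\max_{a,b} 100\,|n_a - n_b| / N$;
* **within-factor imbalance** — for each factor, the largest
  percentage-point difference between two arms in the *proportion* of their
  patients in any one category,
  $\max_{c,a,b} 100\,|n_{fca}/n_a - n_{fcb}/n_b|$.

Proportions, not raw counts, are compared: arms of unequal size make counts
incomparable, and a percentage cutoff is only meaningful on the proportion
scale. If an arm is still empty (possible only for tiny $N$) the factor is
reported maximally imbalanced (100) with a warning.

A difference counts as imbalance when it reaches a size-dependent cutoff:
5% for $N \ge 50$, raised for small trials where 5% of $N$ is a negligible
head-count. The schedule is tabulated at $N = 10, 20, 30, 40, \ge 50$ as
40/20/10/10/5 percent. Between tabulated sizes we use a step function —
$N \le 10 \to 40$, $11\text{–}20 \to 20$, $21\text{–}49 \to 10$,
$\ge 50 \to 5$ — assigning each gap the next tabulated cutoff and extending
the $N = 40$ value through 41–49, which the table leaves unspecified. At
scenario level, a design cell is declared **imbalanced** when at least 10%
of replicate trials (the `chance_threshold` of `imbalance_rule()`) exceed
the cutoff on either statistic; imbalance is evaluated once, at the final
$N$, not path-wise.

## The Monte-Carlo engine and the recommended P

`run_replicates()` simulates (by default) 1,000 replicate trials of a
design, pooling classification percentages and recording the fraction of
replicates flagged for each kind of imbalance. `scan_p()` repeats this over
the grid $P \in \{1.0, 0.9, 0.8, 0.7, 0.6, 0.5\}$ and derives:

* the **imbalance onset** — the largest grid $P$ whose verdict is
  imbalanced (none if the design is balanced everywhere);
* the **recommended P** — the smallest balanced grid value above the onset:
  the most random twist the design tolerates without compromising balance.
  When verdicts are monotone in $P$ (the usual regime) this is simply the
  smallest balanced $P$; requiring it to sit above the onset keeps the rule
  well defined when Monte-Carlo noise produces an isolated clean verdict
  below the onset. If even the top of the grid is imbalanced the scan is
  flagged `no_balanced_p`;
* the **predictability reduction** — deterministic percentage at the top of
  the grid minus that at the recommended $P$: what lowering $P$ buys.

`scenario_grid()` runs a battery of designs (e.g.
`two_treatment_battery()`, the thirteen two-arm factor configurations) and
reports one summary row per design.

### Random numbers

A single master seed spawns one L'Ecuyer-CMRG child stream per replicate
(stream id = replicate index), so replicates are order-independent and
results are reproducible byte-for-byte. Each replicate's stream is split
into a cohort sub-stream and an allocation sub-stream, and `scan_p()`
reuses the cohort across the whole $P$ grid (common random numbers): the
reduction-in-predictability columns are differences on shared cohorts,
which sharpens them considerably at 1,000 replicates. Engine functions
save and restore the session RNG state, so they never perturb a user's
own random sequence.

## The synthetic cohort generator

Patients are synthetic: each factor level is drawn independently from its
categorical prevalence distribution, independently across patients. This is
exactly the population model of the simulation study the package
reproduces, and what it does *not* model matters for interpretation:
factors are independent of each other (no correlated prognostic variables),
prevalences are constant over time (no recruitment drift), entry is
sequential with no staggered-entry structure, and there is no dropout and
no outcome model. Passing tests therefore demonstrate properties of the
allocation algorithm under this idealised cohort, not robustness to
real-world cohort structure.

Where "unequal prevalence" scenarios are needed, the exact probabilities
are a convention fixed once for reproducibility (`prevalence_preset()`):
binary $(0.7, 0.3)$, three categories $(0.5, 0.3, 0.2)$, four categories
$(0.4, 0.3, 0.2, 0.1)$. These are documented assumptions — configs always
accept explicit prevalence vectors.

## Numerical and design choices

* Scores and counts are integers; score comparisons are exact, so tie
  detection has no floating-point tolerance.
* Prevalence vectors must sum to 1 within $10^{-9}$ and have entries
  strictly inside $(0, 1)$ with at least two categories; $P$ outside
  $[0.5, 1]$ and $N < 1$ are rejected at construction.
* The first allocation of every trial is necessarily a tie (all scores
  zero). At $P = 1$ the twist branch is unreachable; a twist can never land
  on an arm tied for the minimum, because the twist branch only fires when
  the minimiser is unique.
* Steady-state benchmark percentages are read at $N = 200$ with 1,000
  replicates — the study quotes its large-trial percentages without always
  fixing $N$, and 200 sits inside that regime; this is recorded as the
  package's assumption.
* The worked-example fixture stores the marginal counts (which the
  published table gives) rather than 20 individual patient profiles (which
  it does not determine uniquely); its integrity check is that every factor
  block's column sums are (10, 10). Scoring its 21st patient gives
  $(18, 26)$: the published group-B addends $8 + 9 + 2 + 7$ sum to 26, and
  the package reports the arithmetic result of the counts it ships.

## Verification

The test suite checks the implementation at three levels. Exact: the
worked example, the cutoff schedule, and brute-force oracles for both
imbalance statistics. Exhaustive: a dynamic program enumerates every
marginal-count state for small designs (two arms, up to two binary factors,
$N \le 6$) and computes the exact probability of each classification at
each entry step, against which Monte-Carlo frequencies must fall inside
exact binomial 99% intervals ($10^5$ replicates in the acceptance suite,
$2 \times 10^4$ in the unit suite). Stochastic: 1,000-replicate scenarios
at $N = 200$ (and a $P$ scan at $N = 300$ with three binary factors) must
reproduce the published steady-state percentages within ±3 percentage
points. Property tests cover the classification partition, the absence of
twists at $P = 1$, marginal uniformity at $P = 0.5$ with two arms, the
$|n_A - n_B| \le K$ bound for one $K$-category factor at $P = 1$, and
byte-identical reports under a fixed master seed.

## Limitations

* The predictability measure assumes complete knowledge of all prior
  allocations — a conservative, worst-case observer; centre-stratified
  recruitment, blinding and concealment are outside the model.
* Multi-arm tie-break and twist-distribution conventions (above) are one
  defensible reading; alternative readings would change multi-arm tie and
  twist percentages slightly.
* The recommendation rule operates on the fixed $P$ grid; it does not
  interpolate between grid values, and with 1,000 replicates verdicts near
  the 10% chance threshold are themselves Monte-Carlo estimates.
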