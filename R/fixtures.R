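#' Load the packaged worked example
#'
#' A hypothetical two-arm osteoporotic-fracture trial after 20 patients,
#' minimised on four prognostic factors (gender; age band; type of fracture;
#' time since fracture), together with the incoming 21st patient (female,
#' age <80 years, proximal femur fracture, 0 to 3 months since fracture).
#' Scoring this patient gives marginal totals (18, 27), so with P = 1 the
#' allocation is deterministic to arm A.
#'
#' The fixture ships as a plain CSV of the marginal counts; on load the
#' factor-wise column sums are checked (every factor must account for all 20
#' patients, with arm totals 10 and 10) so a corrupted fixture fails loudly.
#'
#' @return A list with `table` (a [marginal_table()]), `patient` (integer
#'   levels of the 21st patient) and `design` (a 2-arm [minim_design()] whose
#'   prevalences are nominal: the fixture fixes counts, not a population).
#' @examples
#' we <- load_worked_example()
#' marginal_scores(we$table, we$patient)
#' @export
load_worked_example <- function() {
  path <- system.file("extdata", "worked_example.csv", package = "minimsim",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected_cols <- c("factor", "category", "arm_A", "arm_B")
  if (!identical(names(raw), expected_cols))
    stop("worked-example fixture corrupted: unexpected columns", call. = FALSE)

  fac_names <- unique(raw$factor)
  factors <- lapply(fac_names, function(fn) {
    rows <- raw[raw$factor == fn, ]
    k <- nrow(rows)
    factor_spec(fn, rep(1 / k, k), labels = rows$category)
  })
  design <- minim_design(2L, 21L, 1.0, factors)
  counts <- as.matrix(raw[, c("arm_A", "arm_B")])

  # integrity check: every factor accounts for the same 20 patients, 10 per arm
  for (fn in fac_names) {
    block <- counts[raw$factor == fn, , drop = FALSE]
    if (!identical(as.integer(colSums(block)), c(10L, 10L)))
      stop("worked-example fixture corrupted: factor '", fn,
           "' arm totals are not (10, 10)", call. = FALSE)
  }

  tab <- marginal_table(design, counts = counts)
  patient <- c(
    gender = match("female", raw$category[raw$factor == "gender"]),
    age_band = match("<80", raw$category[raw$factor == "age_band"]),
    fracture_type = match("proximal_femur",
                          raw$category[raw$factor == "fracture_type"]),
    time_since_fracture = match("0-3_months",
                                raw$category[raw$factor == "time_since_fracture"])
  )
  if (anyNA(patient))
    stop("worked-example fixture corrupted: missing category labels",
         call. = FALSE)
  list(table = tab, patient = patient, design = design)
}

#' Published reference values
#'
#' Reference rows from the simulation study this package reproduces, shipped
#' as a JSON fixture: the small-trial imbalance cutoff schedule (exact), the
#' steady-state tie/deterministic percentages at P = 1 for each arms x
#' binary-factor combination (stochastic, tolerance +/-3 percentage points),
#' a P-scan reference row, and the maximum-achievable predictability
#' reduction ranges. These are transcriptions used by the test suite to
#' separate "did we copy the benchmark correctly" from "does the simulation
#' reproduce it".
#'
#' @return A named list of data frames: `cutoff_schedule`, `steady_state`,
#'   `pscan_reference`, `max_reduction`.
#' @export
reference_rows <- function() {
  path <- system.file("extdata", "reference_rows.json", package = "minimsim",
                      mustWork = TRUE)
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref$comment <- NULL
  ref
}
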