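#' Define a prognostic factor
#'
#' A prognostic (minimisation) factor is described by its category prevalences:
#' the population probability of a patient presenting with each category.
#'
#' @param name Character label for the factor.
#' @param prevalence Numeric vector of category probabilities, length >= 2.
#'   Each entry must lie in (0, 1) and the vector must sum to 1 (tolerance
#'   1e-9). Names, if present, are used as category labels.
#' @param labels Optional character vector of category labels; defaults to
#'   `names(prevalence)` or `"1"`, `"2"`, ...
#'
#' @return An object of class `factor_spec`.
#' @seealso [prevalence_preset()] for the named unequal-prevalence conventions.
#' @examples
#' factor_spec("gender", c(male = 0.5, female = 0.5))
#' @export
factor_spec <- function(name, prevalence, labels = NULL) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string", call. = FALSE)
  if (!is.numeric(prevalence) || length(prevalence) < 2L)
    stop("factor '", name, "': 'prevalence' must be a numeric vector with >= 2 categories",
         call. = FALSE)
  if (anyNA(prevalence) || any(prevalence <= 0) || any(prevalence >= 1))
    stop("factor '", name, "': prevalence entries must each lie strictly in (0, 1)",
         call. = FALSE)
  if (abs(sum(prevalence) - 1) > 1e-9)
    stop("factor '", name, "': prevalence must sum to 1 (got ",
         format(sum(prevalence), digits = 12), ")", call. = FALSE)
  if (is.null(labels)) labels <- names(prevalence)
  if (is.null(labels)) labels <- as.character(seq_along(prevalence))
  if (length(labels) != length(prevalence))
    stop("factor '", name, "': 'labels' must match the number of categories",
         call. = FALSE)
  structure(
    list(name = name, prevalence = unname(as.numeric(prevalence)),
         labels = as.character(labels)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat("Prognostic factor '", x$name, "': ", length(x$prevalence),
      " categories (", paste0(x$labels, "=", format(x$prevalence), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Named unequal-prevalence conventions
#'
#' The simulation study varies whether category prevalences are equal or not,
#' without pinning particular unequal values. These presets fix one convention
#' per category count so that "unequal prevalence" scenarios are reproducible:
#' binary (0.7, 0.3); three categories (0.5, 0.3, 0.2); four categories
#' (0.4, 0.3, 0.2, 0.1). `"equal"` gives 1/K for each of K categories.
#'
#' @param k Integer number of categories (2, 3 or 4 for `"unequal"`).
#' @param kind `"equal"` or `"unequal"`.
#' @return Numeric prevalence vector of length `k`.
#' @examples
#' prevalence_preset(2, "unequal")  # 0.7 0.3
#' @export
prevalence_preset <- function(k, kind = c("equal", "unequal")) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (kind == "equal") {
    if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
    return(rep(1 / k, k))
  }
  presets <- list(`2` = c(0.7, 0.3), `3` = c(0.5, 0.3, 0.2),
                  `4` = c(0.4, 0.3, 0.2, 0.1))
  p <- presets[[as.character(k)]]
  if (is.null(p))
    stop("no unequal-prevalence preset for k = ", k, "; supply prevalences explicitly",
         call. = FALSE)
  p
}

#' Define a trial scenario
#'
#' Bundles the quantities the simulation study varies: number of treatment
#' arms, trial size N, the probability P of allocating to the optimal arm
#' (the arm with the unique smallest marginal score), and the ordered list of
#' prognostic factors used for minimisation.
#'
#' @param n_arms Integer number of treatment arms, >= 2 (the study explores
#'   2-4).
#' @param n_patients Integer trial size N, >= 1.
#' @param p_optimal Probability P of assigning the optimal arm when the
#'   minimiser of the marginal scores is unique. Must lie in \[0.5, 1\]:
#'   P = 1 is fully deterministic minimisation, P = 0.5 with two arms
#'   degenerates to simple randomisation.
#' @param factors A [factor_spec()], or a list of them. Convenience: a bare
#'   numeric vector (or list of them) is taken as prevalences and wrapped in
#'   auto-named factor specs.
#'
#' @return An object of class `minim_design`.
#' @examples
#' d <- minim_design(2, 200, 1.0, factor_spec("site", c(0.5, 0.5)))
#' d
#' @export
minim_design <- function(n_arms, n_patients, p_optimal, factors) {
  if (length(n_arms) != 1L || is.na(n_arms) || n_arms != as.integer(n_arms) ||
      n_arms < 2)
    stop("'n_arms' must be a single integer >= 2", call. = FALSE)
  if (length(n_patients) != 1L || is.na(n_patients) ||
      n_patients != as.integer(n_patients) || n_patients < 1)
    stop("'n_patients' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(p_optimal) || length(p_optimal) != 1L || is.na(p_optimal) ||
      p_optimal < 0.5 || p_optimal > 1)
    stop("'p_optimal' must lie in [0.5, 1]", call. = FALSE)
  factors <- as_factor_list(factors)
  if (length(factors) < 1L)
    stop("at least one prognostic factor is required", call. = FALSE)

  k <- vapply(factors, function(f) length(f$prevalence), integer(1))
  structure(
    list(
      n_arms = as.integer(n_arms),
      n_patients = as.integer(n_patients),
      p_optimal = as.numeric(p_optimal),
      factors = factors,
      n_categories = k,
      # flattened (factor, category) -> row offset used by the marginal table
      row_offset = c(0L, cumsum(k))[seq_along(k)]
    ),
    class = "minim_design"
  )
}

as_factor_list <- function(factors) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (is.numeric(factors)) factors <- list(factors)
  if (!is.list(factors))
    stop("'factors' must be a factor_spec or a list of them", call. = FALSE)
  lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    if (inherits(f, "factor_spec")) return(f)
    if (is.numeric(f)) return(factor_spec(paste0("factor", i), f))
    stop("'factors[[", i, "]]' is neither a factor_spec nor a prevalence vector",
         call. = FALSE)
  })
}

#' @export
print.minim_design <- function(x, ...) {
  cat("Minimisation trial design\n")
  cat("  arms:", x$n_arms, "  N:", x$n_patients,
      "  P(optimal):", format(x$p_optimal), "\n")
  cat("  factors:\n")
  for (f in x$factors)
    cat("    ", f$name, " (", paste(format(f$prevalence), collapse = "/"),
        ")\n", sep = "")
  invisible(x)
}

#' Sample a synthetic patient or cohort
#'
#' Each patient is a vector of category indices, one per prognostic factor,
#' drawn independently from that factor's categorical prevalence distribution.
#' `sample_cohort()` draws the design's full cohort of `n_patients` patients.
#'
#' Draws consume the session RNG stream, so results are reproducible with
#' `set.seed()` (the engine manages per-replicate streams itself).
#'
#' @param design A [minim_design()].
#' @param n Number of patients to draw (`sample_cohort()` defaults to
#'   `design$n_patients`).
#' @return An integer matrix with one row per patient and one column per
#'   factor; entries are 1-based category indices. `sample_patient()` returns
#'   a single integer vector.
#' @examples
#' d <- minim_design(2, 10, 1.0, list(c(0.5, 0.5), c(1/3, 1/3, 1/3)))
#' set.seed(1)
#' sample_cohort(d)
#' @export
sample_cohort <- function(design, n = design$n_patients) {
  stopifnot(inherits(design, "minim_design"))
  n <- as.integer(n)
  m <- matrix(0L, nrow = n, ncol = length(design$factors))
  for (j in seq_along(design$factors)) {
    p <- design$factors[[j]]$prevalence
    m[, j] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  colnames(m) <- vapply(design$factors, `[[`, character(1), "name")
  m
}

#' @rdname sample_cohort
#' @export
sample_patient <- function(design) {
  drop(sample_cohort(design, n = 1L))
}

#' Read and write scenario configuration files
#'
#' A scenario config is a YAML or JSON document with keys `arms`, `n`, `p`,
#' and `factors` (a list of `{name, prevalence}`), optionally `reps` and
#' `seed`. The round trip config -> design -> config is lossless for the
#' design fields.
#'
#' @param path File path; format is inferred from the extension
#'   (`.json` vs `.yaml`/`.yml`).
#' @return `read_design_config()`: a [minim_design()], with any `reps` and
#'   `seed` keys attached as attributes of the same names.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("arms", "n", "p", "factors"))
    if (is.null(cfg[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  factors <- lapply(cfg$factors, function(f)
    factor_spec(f$name, unlist(f$prevalence)))
  d <- minim_design(cfg$arms, cfg$n, cfg$p, factors)
  if (!is.null(cfg$reps)) attr(d, "reps") <- as.integer(cfg$reps)
  if (!is.null(cfg$seed)) attr(d, "seed") <- as.integer(cfg$seed)
  d
}

#' @rdname read_design_config
#' @param design A [minim_design()] to serialise.
#' @param reps,seed Optional replicate count and master seed to embed.
#' @export
write_design_config <- function(design, path, reps = NULL, seed = NULL) {
  stopifnot(inherits(design, "minim_design"))
  cfg <- list(
    arms = design$n_arms, n = design$n_patients, p = design$p_optimal,
    factors = lapply(design$factors, function(f)
      list(name = f$name, prevalence = f$prevalence))
  )
  if (!is.null(reps)) cfg$reps <- as.integer(reps)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
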