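# Seeded synthetic patient cohorts with the statistical structure of the
# institutional case study, so the case-study pipeline is fully testable
# without patient-level data (which was never published).
#
# Test counts per patient follow a truncated shifted Poisson (support
# {min..max}, min >= 1) whose rate is calibrated so the truncated mean equals
# the profile mean; mutation counts follow a truncated (unshifted) Poisson
# calibrated the same way, which keeps cohort-level estimates convergent to
# the profile values even when the truncation binds. Tests are drawn without
# replacement by weight, falling back to with-replacement draws once the
# distinct catalog entries of the mix are exhausted (repeat entries model the
# same assay class applied to different genes). Category flags are
# independent Bernoulli draws.

#' Define a synthetic cohort profile
#'
#' @param indication `"nsclc"` or `"melanoma"`.
#' @param period `"before"` or `"after"`.
#' @param n_patients Number of patients to generate.
#' @param tests_mean,tests_min,tests_max Target mean and range of the number
#'   of tests per patient (`tests_min >= 1`,
#'   `tests_min <= tests_mean <= tests_max`).
#' @param test_mix Named non-negative selection weights over catalog entries
#'   (not all zero).
#' @param mutation_mean,mutation_min,mutation_max Target mean and range of
#'   the mutation count per patient.
#' @param category_probs Named probabilities in [0, 1] for the
#'   [table_categories()] flags; omitted categories default to 0.
#' @return A `cohort_profile` object.
#' @export
cohort_profile <- function(indication, period, n_patients,
                           tests_mean, tests_min, tests_max, test_mix,
                           mutation_mean, mutation_min = 0L, mutation_max,
                           category_probs = numeric()) {
  check_number(n_patients, "n_patients", min = 1)
  check_number(tests_min, "tests_min", min = 1)
  if (tests_mean < tests_min || tests_mean > tests_max) {
    stop(sprintf("infeasible profile: tests_mean %.3g outside [%g, %g]",
                 tests_mean, tests_min, tests_max), call. = FALSE)
  }
  if (mutation_mean < mutation_min || mutation_mean > mutation_max) {
    stop(sprintf("infeasible profile: mutation_mean %.3g outside [%g, %g]",
                 mutation_mean, mutation_min, mutation_max), call. = FALSE)
  }
  if (length(test_mix) == 0L || is.null(names(test_mix)) ||
      any(test_mix < 0) || sum(test_mix) <= 0) {
    stop("`test_mix` must be named, non-negative and not all zero",
         call. = FALSE)
  }
  if (any(category_probs < 0 | category_probs > 1)) {
    stop("`category_probs` must lie in [0, 1]", call. = FALSE)
  }
  probs <- stats::setNames(rep(0, length(table_categories())),
                           table_categories())
  unknown <- setdiff(names(category_probs), names(probs))
  if (length(unknown) > 0L) {
    stop("unknown categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  probs[names(category_probs)] <- category_probs
  structure(list(indication = indication, period = period,
                 n_patients = as.integer(n_patients),
                 tests_mean = tests_mean,
                 tests_min = as.integer(tests_min),
                 tests_max = as.integer(tests_max),
                 test_mix = test_mix[test_mix > 0],
                 mutation_mean = mutation_mean,
                 mutation_min = as.integer(mutation_min),
                 mutation_max = as.integer(mutation_max),
                 category_probs = probs),
            class = "cohort_profile")
}

# pmf of a Poisson truncated to `support`, shifted by `shift`; normalised in
# log space so large rates do not underflow
truncated_poisson_pmf <- function(support, lambda, shift) {
  lp <- stats::dpois(support - shift, lambda, log = TRUE)
  p <- exp(lp - max(lp))
  p / sum(p)
}

# rate such that the truncated (shifted) Poisson mean equals target_mean
calibrate_truncated_poisson <- function(target_mean, lo, hi, shift) {
  support <- lo:hi
  if (length(support) == 1L || target_mean <= lo + 1e-12) {
    return(list(support = support, pmf = c(1, rep(0, length(support) - 1L))))
  }
  if (target_mean >= hi - 1e-12) {
    return(list(support = support,
                pmf = c(rep(0, length(support) - 1L), 1)))
  }
  f <- function(lambda) {
    sum(support * truncated_poisson_pmf(support, lambda, shift)) - target_mean
  }
  lambda <- stats::uniroot(f, c(1e-9, 10 * (hi - shift) + 10),
                           extendInt = "upX", tol = 1e-10)$root
  list(support = support, pmf = truncated_poisson_pmf(support, lambda, shift))
}

# draw one patient's set of tests: without replacement by weight while
# distinct entries last, then with replacement
draw_tests <- function(k, mix) {
  names_mix <- names(mix)
  if (k <= length(mix)) {
    sample(names_mix, k, replace = FALSE, prob = mix)
  } else {
    extra <- sample(names_mix, k - length(mix), replace = TRUE, prob = mix)
    c(sample(names_mix, length(mix), replace = FALSE, prob = mix), extra)
  }
}

# generator core: consumes the current RNG stream
r_cohort <- function(profile) {
  n <- profile$n_patients
  tests_dist <- calibrate_truncated_poisson(profile$tests_mean,
                                            profile$tests_min,
                                            profile$tests_max, shift = 1L)
  mut_dist <- calibrate_truncated_poisson(profile$mutation_mean,
                                          profile$mutation_min,
                                          profile$mutation_max, shift = 0L)
  n_tests <- sample(tests_dist$support, n, replace = TRUE,
                    prob = tests_dist$pmf)
  mutations <- sample(mut_dist$support, n, replace = TRUE,
                      prob = mut_dist$pmf)
  tests <- vapply(n_tests, function(k)
    paste(draw_tests(k, profile$test_mix), collapse = ";"), character(1))
  flags <- lapply(profile$category_probs, function(p)
    stats::rbinom(n, 1L, p) == 1L)
  out <- data.frame(
    patient_id = sprintf("%s_%s_%03d", profile$indication, profile$period,
                         seq_len(n)),
    indication = profile$indication, period = profile$period,
    tests = tests, mutation_count = mutations,
    stringsAsFactors = FALSE)
  for (cat in names(flags)) out[[cat]] <- flags[[cat]]
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws `profile$n_patients` patient records reproducing the profile's test
#' count distribution, test mix, mutation count distribution and category
#' prevalences in expectation. Identical `(profile, seed)` yields an
#' identical cohort.
#'
#' @param profile A [cohort_profile()].
#' @param seed Integer seed.
#' @return Patient-record data frame (see [read_patient_records()] for the
#'   column layout).
#' @examples
#' cohort <- generate_cohort(table_profile("nsclc_before"), seed = 1)
#' @export
generate_cohort <- function(profile, seed) {
  stopifnot(inherits(profile, "cohort_profile"))
  set.seed(seed)
  r_cohort(profile)
}

#' Generate a before/after cohort pair
#'
#' Two independent cohorts drawn from one seeded stream, ready for
#' [compare_periods()].
#'
#' @param before_profile,after_profile [cohort_profile()]s with the same
#'   indication.
#' @param seed Integer seed.
#' @return List with elements `before` and `after`.
#' @export
paired_cohorts <- function(before_profile, after_profile, seed) {
  stopifnot(inherits(before_profile, "cohort_profile"),
            inherits(after_profile, "cohort_profile"))
  if (before_profile$indication != after_profile$indication) {
    stop("profiles have different indications", call. = FALSE)
  }
  set.seed(seed)
  list(before = r_cohort(before_profile), after = r_cohort(after_profile))
}
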