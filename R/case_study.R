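# Institutional before/after comparison of molecular-testing records.
#
# Patient records are a plain data frame: one row per patient, with the
# tests received as a semicolon-separated string of catalog entries, the
# number of observed mutations, and one logical column per treatment /
# mutation category. The pipeline summarises each period, compares periods
# variable by variable with a rule-based choice of statistical test, and
# annualises the observation window to an institutional budget impact.

#' Treatment and mutation category names
#'
#' The binary per-patient categories tracked in the case study: availability
#' of an (EMA-approved or trial) targeted therapy for an observed mutation,
#' and the treatment actually started.
#'
#' @return Character vector of 12 category names.
#' @export
table_categories <- function() {
  c("ema_tt_available", "trial_tt_available", "started_ema_tt",
    "included_tt_trial", "tt_option_no_start", "trial_without_tt",
    "started_mab", "started_mab_trial", "started_radio_chemo",
    "started_operation", "no_treatment_option", "treated_elsewhere")
}

record_columns <- function() {
  c("patient_id", "indication", "period", "tests", "mutation_count",
    table_categories())
}

validate_records <- function(records) {
  missing <- setdiff(record_columns(), names(records))
  if (length(missing) > 0L) {
    stop("patient records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records$tests))) {
    stop("every patient record must list at least one test", call. = FALSE)
  }
  if (any(records$mutation_count < 0)) {
    stop("`mutation_count` must be non-negative", call. = FALSE)
  }
  invisible(records)
}

split_tests <- function(records) strsplit(records$tests, ";", fixed = TRUE)

record_costs <- function(records, catalog) {
  vapply(split_tests(records),
         function(tests) sum(catalog_price(catalog, tests)), numeric(1))
}

#' Read / write patient records as CSV
#'
#' Columns: `patient_id`, `indication`, `period`, `tests`
#' (semicolon-separated catalog entries), `mutation_count`, and one logical
#' column per [table_categories()] entry.
#'
#' @param path CSV file.
#' @param records Patient-record data frame.
#' @return `read_patient_records()` returns the validated data frame;
#'   `write_patient_records()` returns `path` invisibly.
#' @export
read_patient_records <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cat in table_categories()) {
    if (cat %in% names(records)) records[[cat]] <- as.logical(records[[cat]])
  }
  validate_records(records)
}

#' @rdname read_patient_records
#' @export
write_patient_records <- function(records, path) {
  validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Summarise one period of patient records
#'
#' Per-patient derived measures (number of tests, test cost, cost per test,
#' mutation count) aggregated to mean/min/max, plus counts and percentages
#' for the binary categories.
#'
#' @param records Patient records of one indication and period.
#' @param catalog A [test_catalog()] resolving every test name.
#' @return A `period_summary` object: `n_patients`, `stats` (data frame
#'   `variable`/`mean`/`min`/`max`), `category_counts` (data frame
#'   `category`/`count`/`percent`).
#' @export
summarize_period <- function(records, catalog) {
  validate_records(records)
  if (nrow(records) == 0L) stop("no records to summarise", call. = FALSE)
  if (length(unique(records$indication)) != 1L ||
      length(unique(records$period)) != 1L) {
    stop("records must share one indication and one period", call. = FALSE)
  }
  n_tests <- lengths(split_tests(records))
  cost <- record_costs(records, catalog)
  vars <- list(tests_per_patient = n_tests,
               cost_per_patient = cost,
               cost_per_test = cost / n_tests,
               mutations_per_patient = records$mutation_count)
  stats <- data.frame(
    variable = names(vars),
    mean = vapply(vars, mean, numeric(1)),
    min = vapply(vars, min, numeric(1)),
    max = vapply(vars, max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- vapply(table_categories(), function(cat)
    sum(records[[cat]]), numeric(1))
  structure(
    list(indication = records$indication[[1]], period = records$period[[1]],
         n_patients = nrow(records), stats = stats,
         category_counts = data.frame(
           category = table_categories(), count = unname(counts),
           percent = unname(100 * counts / nrow(records)),
           stringsAsFactors = FALSE)),
    class = "period_summary")
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf("<period_summary> %s, period '%s', n = %d\n",
              x$indication, x$period, x$n_patients))
  print(transform(x$stats, mean = round(mean, 2)), row.names = FALSE)
  invisible(x)
}

#' Statistical test selection rule
#'
#' Continuous variables with a normal distribution in both groups are
#' compared with an independent two-sample t-test, continuous variables
#' without with a Mann-Whitney U-test, binary variables with Fisher's exact
#' test.
#'
#' @param variable_kind `"continuous"` or `"binary"`.
#' @param normal Logical; is the variable normally distributed (ignored for
#'   binary variables)?
#' @return `"t"`, `"mann_whitney"` or `"fisher"`.
#' @export
select_test <- function(variable_kind = c("continuous", "binary"), normal) {
  variable_kind <- match.arg(variable_kind)
  if (variable_kind == "binary") return("fisher")
  if (isTRUE(normal)) "t" else "mann_whitney"
}

group_is_normal <- function(x, alpha) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

compare_continuous <- function(before, after, alpha, normality_alpha) {
  spread <- function(x) if (length(x) < 2L) 0 else stats::var(x)
  if (spread(before) == 0 && spread(after) == 0) {
    return(list(test = NA_character_, p = NA_real_, note = "degenerate: zero variance in both groups"))
  }
  normal <- group_is_normal(before, normality_alpha) &&
    group_is_normal(after, normality_alpha)
  test <- select_test("continuous", normal)
  p <- if (test == "t") {
    stats::t.test(before, after)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(before, after, exact = NULL))$p.value
  }
  list(test = test, p = p, note = NA_character_)
}

#' Compare the before and after periods
#'
#' One row per case-study variable: the four continuous per-patient measures
#' (tests, cost, cost per test, mutations) and the binary categories, each
#' compared with the test chosen by [select_test()] (normality assessed per
#' group with a Shapiro-Wilk test). Two-sided p-values; binary variables as
#' 2x2 Fisher's exact tests.
#'
#' @param before,after Patient records of the two periods (same indication).
#' @param catalog A [test_catalog()].
#' @param alpha Significance level (default 0.05).
#' @param normality_alpha Level of the per-group normality assessment
#'   (default 0.05).
#' @return Data frame with columns `variable`, `kind`, `test`, `p_value`,
#'   `significant`, `note`.
#' @export
compare_periods <- function(before, after, catalog, alpha = 0.05,
                            normality_alpha = 0.05) {
  validate_records(before)
  validate_records(after)
  if (nrow(before) == 0L || nrow(after) == 0L) {
    stop("both periods need at least one record", call. = FALSE)
  }
  cont_vars <- function(records) {
    n_tests <- lengths(split_tests(records))
    cost <- record_costs(records, catalog)
    list(tests_per_patient = n_tests, cost_per_patient = cost,
         cost_per_test = cost / n_tests,
         mutations_per_patient = records$mutation_count)
  }
  vb <- cont_vars(before)
  va <- cont_vars(after)
  rows <- lapply(names(vb), function(v) {
    res <- compare_continuous(vb[[v]], va[[v]], alpha, normality_alpha)
    data.frame(variable = v, kind = "continuous", test = res$test,
               p_value = res$p,
               significant = !is.na(res$p) && res$p < alpha,
               note = res$note, stringsAsFactors = FALSE)
  })
  bin_rows <- lapply(table_categories(), function(cat) {
    tab <- matrix(c(sum(before[[cat]]), nrow(before) - sum(before[[cat]]),
                    sum(after[[cat]]), nrow(after) - sum(after[[cat]])),
                  nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(variable = cat, kind = "binary", test = "fisher",
               p_value = p, significant = p < alpha, note = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, bin_rows))
  rownames(out) <- NULL
  out
}

#' Annualise an observation window
#'
#' Scales the number of patients seen in the observation window to a full
#' year (assuming the window is representative) and prices each period's
#' yearly population at that period's mean cost per patient.
#'
#' @param records Patient records covering both periods.
#' @param observation_months Length of the observation window in months
#'   (positive).
#' @param catalog A [test_catalog()].
#' @return List with `yearly_patients` (integer) and
#'   `population_cost_per_period` (named numeric, euros/year per period,
#'   unrounded).
#' @examples
#' # 100 patients over 3.5 months ~ 343 patients/year
#' @export
annualize <- function(records, observation_months, catalog) {
  validate_records(records)
  check_number(observation_months, "observation_months", min = 0,
               strict_min = TRUE)
  if (nrow(records) == 0L) stop("no patients to annualise", call. = FALSE)
  yearly <- as.integer(round_euro(nrow(records) / observation_months * 12))
  periods <- unique(records$period)
  pop <- vapply(periods, function(p) {
    rows <- records[records$period == p, , drop = FALSE]
    yearly * mean(record_costs(rows, catalog))
  }, numeric(1))
  list(yearly_patients = yearly,
       population_cost_per_period = stats::setNames(pop, periods))
}

#' Institutional budget impact of the implementation
#'
#' Per-patient delta = after-period mean cost minus before-period mean cost;
#' population delta scales it by the yearly institutional patient count.
#' Computed on unrounded values; round with [round_euro()] for reporting.
#'
#' @param before_summary,after_summary [summarize_period()] results sharing
#'   an indication.
#' @param yearly_patients Yearly institutional patient count.
#' @return A `budget_impact` object.
#' @export
institutional_budget_impact <- function(before_summary, after_summary,
                                        yearly_patients) {
  stopifnot(inherits(before_summary, "period_summary"),
            inherits(after_summary, "period_summary"))
  if (before_summary$indication != after_summary$indication) {
    stop("summaries compare different indications", call. = FALSE)
  }
  mean_cost <- function(s) {
    s$stats$mean[s$stats$variable == "cost_per_patient"]
  }
  delta <- mean_cost(after_summary) - mean_cost(before_summary)
  structure(list(from_timeframe = before_summary$period,
                 to_timeframe = after_summary$period,
                 indication = before_summary$indication,
                 per_patient_delta = delta,
                 population_delta = yearly_patients * delta),
            class = "budget_impact")
}
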