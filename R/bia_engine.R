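# Deterministic budget impact analysis over time frames and hospital strata,
# following the ISPOR good-practice structure: target population, scenario
# mix per hospital stratum, resource utilisation as test bundles, unit costs
# from a catalog, total costs, and (in sensitivity.R) one-way sensitivity
# analyses. Molecular diagnostics is costed once per newly diagnosed
# stage-IV patient; fractional applicability of a test within a bundle is an
# expected cost, not patient-level sampling.

#' Construct a unit-cost test catalog
#'
#' @param x Named numeric vector (names = test identifiers, values = unit
#'   costs in euros) or a data frame with columns `test` and `unit_cost`.
#' @return A `test_catalog` data frame.
#' @export
test_catalog <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- data.frame(test = names(x), unit_cost = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("test", "unit_cost") %in% names(x)))
  if (anyDuplicated(x$test)) {
    stop("duplicate test names in catalog: ",
         paste(unique(x$test[duplicated(x$test)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(x$unit_cost <= 0)) {
    stop("catalog unit costs must be positive; offending test(s): ",
         paste(x$test[x$unit_cost <= 0], collapse = ", "), call. = FALSE)
  }
  structure(x[, c("test", "unit_cost")], class = c("test_catalog", "data.frame"))
}

catalog_price <- function(catalog, tests) {
  idx <- match(tests, catalog$test)
  if (anyNA(idx)) {
    stop("test(s) not in catalog: ",
         paste(unique(tests[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  catalog$unit_cost[idx]
}

#' Construct a test bundle
#'
#' A bundle is the set of tests one patient receives in one scenario cell,
#' each with an applicability fraction in (0, 1] (e.g. a confirmatory test
#' requested for half of the patients contributes with fraction 0.5). The
#' same catalog entry may appear more than once (distinct genes tested with
#' the same assay class).
#'
#' @param items Data frame with columns `test` and `fraction`, or a list of
#'   `list(test =, fraction =)` pairs.
#' @return A `test_bundle` data frame.
#' @export
test_bundle <- function(items) {
  if (!is.data.frame(items)) {
    items <- do.call(rbind, lapply(items, function(it) {
      data.frame(test = it$test, fraction = it$fraction %||% 1,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(items) || nrow(items) == 0L) {
    items <- data.frame(test = character(), fraction = numeric())
  }
  if (any(items$fraction <= 0 | items$fraction > 1)) {
    stop("bundle fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(items[, c("test", "fraction")], class = c("test_bundle", "data.frame"))
}

#' Expected cost of a test bundle
#'
#' Sum of applicability fraction times catalog unit cost, unrounded.
#'
#' @param bundle A [test_bundle()] (or coercible data frame / list).
#' @param catalog A [test_catalog()].
#' @return Euros (unrounded).
#' @examples
#' cat <- test_catalog(c(small_tgp = 606, single_gene_sanger = 295))
#' bundle_cost(test_bundle(data.frame(
#'   test = c("small_tgp", "single_gene_sanger"),
#'   fraction = c(1, 0.5))), cat)  # 753.5
#' @export
bundle_cost <- function(bundle, catalog) {
  if (!inherits(bundle, "test_bundle")) bundle <- test_bundle(bundle)
  if (nrow(bundle) == 0L) return(0)
  sum(bundle$fraction * catalog_price(catalog, bundle$test))
}

scenario_cells <- function(config, timeframe, indication) {
  keep <- vapply(config$scenarios, function(s) {
    s$timeframe == timeframe && s$indication == indication
  }, logical(1))
  cells <- config$scenarios[keep]
  if (length(cells) == 0L) {
    stop("no scenarios configured for ", timeframe, " / ", indication,
         call. = FALSE)
  }
  cells
}

#' Stratum-weighted diagnostic cost per patient
#'
#' The expected molecular-diagnostic cost of one newly diagnosed patient in
#' a time frame: the patient-share-weighted mean of the per-stratum bundle
#' costs. Stratum shares must sum to one. With `use_printed = TRUE`
#' (default) a scenario's published bundle cost is used where the
#' configuration provides one; otherwise the bundle is priced from the
#' catalog.
#'
#' @param config A `bia_config` (see [load_bia_config()]).
#' @param timeframe,indication Scenario coordinates, e.g. `"old_2012"`,
#'   `"nsclc"`.
#' @param use_printed Prefer configured `printed_cost` values (default TRUE).
#' @return Euros per patient (unrounded).
#' @export
weighted_cost_per_patient <- function(config, timeframe, indication,
                                      use_printed = TRUE) {
  cells <- scenario_cells(config, timeframe, indication)
  shares <- vapply(cells, `[[`, numeric(1), "patient_share")
  if (abs(sum(shares) - 1) > 1e-9) {
    stop(sprintf("stratum shares for %s / %s sum to %.10g, not 1",
                 timeframe, indication, sum(shares)), call. = FALSE)
  }
  costs <- vapply(cells, function(s) {
    if (use_printed && !is.null(s$printed_cost)) s$printed_cost
    else bundle_cost(s$bundle, config$catalog)
  }, numeric(1))
  sum(shares * costs)
}

#' Population-level diagnostic cost per year
#'
#' Patients per year in the frame times the stratum-weighted cost per
#' patient, on unrounded values.
#'
#' @inheritParams weighted_cost_per_patient
#' @return Euros per year (unrounded).
#' @export
population_cost <- function(config, timeframe, indication, use_printed = TRUE) {
  patients <- config$populations[[indication]][[timeframe]]
  if (is.null(patients)) {
    stop("no population configured for ", timeframe, " / ", indication,
         call. = FALSE)
  }
  patients * weighted_cost_per_patient(config, timeframe, indication,
                                       use_printed = use_printed)
}

#' Budget impact between two time frames
#'
#' Differences of unrounded per-patient and population costs; positive values
#' are cost increases.
#'
#' @param config A `bia_config`.
#' @param from,to Time frames.
#' @param indication `"nsclc"` or `"melanoma"`.
#' @param use_printed Prefer configured `printed_cost` values (default TRUE).
#' @return An object of class `budget_impact` with unrounded fields
#'   `per_patient_delta` and `population_delta`.
#' @export
budget_impact <- function(config, from, to, indication, use_printed = TRUE) {
  pp_from <- weighted_cost_per_patient(config, from, indication, use_printed)
  pp_to <- weighted_cost_per_patient(config, to, indication, use_printed)
  pop_from <- config$populations[[indication]][[from]] * pp_from
  pop_to <- config$populations[[indication]][[to]] * pp_to
  structure(list(from_timeframe = from, to_timeframe = to,
                 indication = indication,
                 per_patient_delta = pp_to - pp_from,
                 population_delta = pop_to - pop_from),
            class = "budget_impact")
}

#' @export
print.budget_impact <- function(x, ...) {
  cat(sprintf("<budget_impact> %s: %s -> %s\n",
              x$indication, x$from_timeframe, x$to_timeframe))
  cat(sprintf("  per patient   EUR %s\n",
              format(round_euro(x$per_patient_delta), big.mark = ",")))
  cat(sprintf("  population    EUR %s/year\n",
              format(round_euro(x$population_delta), big.mark = ",")))
  invisible(x)
}

#' Projected whole-genome sequencing price per patient
#'
#' Price of sequencing one patient (several genomes: tumour in triplicate
#' plus a germline reference) after an assumed cost reduction, converted to
#' euros.
#'
#' @param usd_per_genome Current production cost of one genome in US dollars.
#' @param genomes_per_patient Genomes sequenced per patient (default 4).
#' @param reduction_fraction Assumed fractional price reduction over the
#'   projection horizon, in [0, 1) (default 0.75 over five years).
#' @param usd_to_eur Dollar-to-euro conversion rate (default 0.88).
#' @return Euros per patient (unrounded).
#' @examples
#' wgs_price_projection(1250)  # ~1100
#' @export
wgs_price_projection <- function(usd_per_genome, genomes_per_patient = 4L,
                                 reduction_fraction = 0.75, usd_to_eur = 0.88) {
  check_number(usd_per_genome, "usd_per_genome", min = 0, strict_min = TRUE)
  check_number(genomes_per_patient, "genomes_per_patient", min = 1)
  check_number(reduction_fraction, "reduction_fraction", min = 0)
  if (reduction_fraction >= 1) {
    stop("`reduction_fraction` must be < 1", call. = FALSE)
  }
  check_number(usd_to_eur, "usd_to_eur", min = 0, strict_min = TRUE)
  usd_per_genome * genomes_per_patient * (1 - reduction_fraction) * usd_to_eur
}

#' Reconstruct the national BIA summary table
#'
#' Per-patient and population costs for every time frame and indication,
#' plus the budget impacts between consecutive frames. Cost columns are
#' reported in whole euros ([round_euro()]); deltas are computed on
#' unrounded values before rounding.
#'
#' @param config A `bia_config`; defaults to the packaged configuration.
#' @return Data frame with columns `timeframe`, `indication`,
#'   `cost_per_patient`, `population_cost`, `delta_per_patient`,
#'   `delta_population` (deltas relative to the preceding frame; NA for the
#'   first frame).
#' @export
bia_table <- function(config = default_bia_config()) {
  frames <- c("old_2012", "current_2015", "future_2020")
  rows <- list()
  for (ind in names(config$populations)) {
    pp <- vapply(frames, function(tf)
      weighted_cost_per_patient(config, tf, ind), numeric(1))
    pop <- vapply(frames, function(tf)
      population_cost(config, tf, ind), numeric(1))
    rows[[ind]] <- data.frame(
      timeframe = frames, indication = ind,
      cost_per_patient = round_euro(pp),
      population_cost = round_euro(pop),
      delta_per_patient = round_euro(c(NA, diff(pp))),
      delta_population = round_euro(c(NA, diff(pop))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
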