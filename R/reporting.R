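# Configuration validation and table/figure-data export: the glue that ties
# the costing, BIA, sensitivity and case-study modules into one reproducible
# pipeline with CSV outputs.

#' Validate a raw BIA configuration
#'
#' Schema-checks a parsed configuration (catalog, populations, scenarios)
#' before any computation: positive unique catalog prices, bundle fractions
#' in (0, 1], every bundle test resolvable, stratum shares summing to one per
#' time frame and indication, positive population counts. Violations are
#' reported with their location in the file.
#'
#' @param raw Parsed configuration list (e.g. from [yaml::read_yaml()]).
#' @param source Optional file name used in error messages.
#' @return A validated `bia_config` object (catalog coerced to
#'   [test_catalog()], bundles to [test_bundle()]).
#' @export
validate_config <- function(raw, source = "config") {
  fail <- function(path, msg) {
    stop(sprintf("%s: %s: %s", source, path, msg), call. = FALSE)
  }
  for (section in c("catalog", "populations", "scenarios")) {
    if (is.null(raw[[section]])) fail(section, "section missing")
  }
  catalog <- tryCatch(test_catalog(unlist(raw$catalog)),
                      error = function(e) fail("catalog", conditionMessage(e)))
  for (ind in names(raw$populations)) {
    for (tf in names(raw$populations[[ind]])) {
      n <- raw$populations[[ind]][[tf]]
      if (!is.numeric(n) || n <= 0) {
        fail(paste0("populations/", ind, "/", tf),
             "patients per year must be positive")
      }
    }
  }
  scenarios <- lapply(seq_along(raw$scenarios), function(i) {
    s <- raw$scenarios[[i]]
    path <- sprintf("scenarios[%d]", i)
    for (field in c("timeframe", "indication", "stratum", "patient_share",
                    "bundle")) {
      if (is.null(s[[field]])) fail(path, paste0("field `", field, "` missing"))
    }
    if (s$patient_share < 0 || s$patient_share > 1) {
      fail(path, "patient_share must lie in [0, 1]")
    }
    s$bundle <- tryCatch(test_bundle(s$bundle),
                         error = function(e) fail(path, conditionMessage(e)))
    bad <- setdiff(s$bundle$test, catalog$test)
    if (length(bad) > 0L) {
      fail(path, paste("bundle test(s) not in catalog:",
                       paste(bad, collapse = ", ")))
    }
    s
  })
  key <- vapply(scenarios, function(s)
    paste(s$timeframe, s$indication, sep = "/"), character(1))
  for (k in unique(key)) {
    total <- sum(vapply(scenarios[key == k], `[[`, numeric(1),
                        "patient_share"))
    if (abs(total - 1) > 1e-9) {
      fail(paste0("scenarios/", k),
           sprintf("stratum shares sum to %.10g, not 1", total))
    }
  }
  structure(list(catalog = catalog, populations = raw$populations,
                 scenarios = scenarios,
                 sensitivity = raw$sensitivity,
                 wgs_projection = raw$wgs_projection,
                 source = source),
            class = "bia_config")
}

#' Run the full packaged analysis
#'
#' Recomputes every table and figure-data series of the packaged analysis
#' from the configuration: the panel cost decompositions and per-sample
#' costs, the cost-per-sample curves, the national BIA summary, the three
#' tornado analyses, and the synthetic-cohort case study.
#'
#' @param config A `bia_config`; defaults to the packaged configuration.
#' @param seed Integer seed for the synthetic case-study cohorts.
#' @return Named list of data frames (`table1`, `fig2_curve`, `table3`,
#'   `tornado_current_cost`, `tornado_future_nsclc`,
#'   `tornado_future_melanoma`, `case_table4`, `case_table5`) plus `seed`.
#' @export
run_full_analysis <- function(config = default_bia_config(), seed = 1L) {
  combos <- expand.grid(panel = c("small_tgp", "medium_tgp"),
                        platform = c("miseq", "hiseq"),
                        stringsAsFactors = FALSE)
  table1 <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    spec <- panel_spec(combos$panel[i], combos$platform[i])
    plan <- run_plan(min(24L, spec$max_samples_per_run), 1, 0.85)
    data.frame(panel = spec$panel, platform = spec$platform,
               fixed_yearly = round_euro(spec$fixed_yearly),
               fixed_per_run_personnel = round_euro(spec$fixed_per_run_personnel),
               fixed_per_run_material = round_euro(spec$fixed_per_run_material),
               variable_per_sample_personnel = round_euro(spec$variable_per_sample_personnel),
               variable_per_sample_material = round_euro(spec$variable_per_sample_material),
               cost_per_sample_base_plan = round_euro(
                 cost_per_sample(spec, plan)$cost_per_patient_sample),
               stringsAsFactors = FALSE)
  }))
  fig2 <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    spec <- panel_spec(combos$panel[i], combos$platform[i])
    curve <- cost_curve(spec, sample_counts = seq(4L, spec$max_samples_per_run))
    data.frame(panel = spec$panel, platform = spec$platform,
               samples_per_run = curve$samples_per_run,
               cost_per_sample_eur = round_euro(curve$cost_per_sample),
               stringsAsFactors = FALSE)
  }))
  tornado_for <- function(ind) {
    out <- tornado(future_bia_model(config, ind),
                   future_bia_params(config, ind))
    cbind(indication = ind, out)
  }
  arms <- c(before = "%s_before", after = "%s_after")
  case4 <- list(); case5 <- list()
  for (ind in c("nsclc", "melanoma")) {
    cohorts <- paired_cohorts(table_profile(sprintf(arms[["before"]], ind)),
                              table_profile(sprintf(arms[["after"]], ind)),
                              seed = seed)
    summaries <- lapply(cohorts, summarize_period, catalog = config$catalog)
    comparison <- compare_periods(cohorts$before, cohorts$after,
                                  config$catalog)
    stats_wide <- merge(summaries$before$stats, summaries$after$stats,
                        by = "variable", suffixes = c("_before", "_after"))
    case4[[ind]] <- cbind(indication = ind,
                          merge(stats_wide,
                                comparison[comparison$kind == "continuous",
                                           c("variable", "test", "p_value")],
                                by = "variable"))
    both <- rbind(cohorts$before, cohorts$after)
    ann <- annualize(both, observation_months = 3.5, config$catalog)
    impact <- institutional_budget_impact(summaries$before, summaries$after,
                                          ann$yearly_patients)
    case5[[ind]] <- data.frame(
      indication = ind, yearly_patients = ann$yearly_patients,
      cost_per_patient_before = round_euro(
        summaries$before$stats$mean[summaries$before$stats$variable == "cost_per_patient"]),
      cost_per_patient_after = round_euro(
        summaries$after$stats$mean[summaries$after$stats$variable == "cost_per_patient"]),
      population_cost_before = round_euro(ann$population_cost_per_period[["before"]]),
      population_cost_after = round_euro(ann$population_cost_per_period[["after"]]),
      budget_impact_per_patient = round_euro(impact$per_patient_delta),
      budget_impact_population = round_euro(impact$population_delta),
      stringsAsFactors = FALSE)
  }
  list(table1 = table1,
       fig2_curve = fig2,
       table3 = bia_table(config),
       tornado_current_cost = current_cost_sensitivity(catalog = config$catalog),
       tornado_future_nsclc = tornado_for("nsclc"),
       tornado_future_melanoma = tornado_for("melanoma"),
       case_table4 = do.call(rbind, case4),
       case_table5 = do.call(rbind, case5),
       seed = seed)
}

#' Export analysis results as CSV files
#'
#' Writes every data frame in `results` as `<name>.csv` under `dir`, plus a
#' `manifest.json` recording the package version, seed and file list. Euro
#' columns are written as plain integers (no separators) to keep the files
#' machine-readable; outputs carry no timestamps, so identical results yield
#' byte-identical files.
#'
#' @param results Named list of data frames, e.g. from
#'   [run_full_analysis()]; an empty data frame yields a header-only file.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_df <- vapply(results, is.data.frame, logical(1))
  paths <- character()
  for (name in names(results)[is_df]) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(results[[name]], path, row.names = FALSE, quote = TRUE)
    paths <- c(paths, path)
  }
  manifest <- list(
    package = "panelcost",
    version = as.character(utils::packageVersion("panelcost")),
    seed = results$seed %||% NA,
    files = basename(paths))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest_path))
}
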