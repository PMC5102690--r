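# Activity-based costing of NGS panel tests.
#
# The cost of one panel test is decomposed into three layers: fixed yearly
# costs (equipment depreciation and service), fixed costs per run (personnel
# and material consumed by a run regardless of how many samples it carries)
# and variable costs per sample. The cost per patient sample then depends on
# the run plan: how many samples are booked per run, how many runs are
# executed per week, and which fraction of the booked capacity is actually
# used. Control samples consume variable costs only; their cost is spread
# over the patient samples of the run.

#' Construct one activity step of a panel workflow
#'
#' An activity step is one resource-consuming action of the laboratory
#' workflow: personnel minutes (per sample and/or per run), material costs
#' (per sample and/or per run) and annualised equipment costs.
#'
#' @param label Free-text description of the step.
#' @param role Personnel category performing the step; one of
#'   `"secretary"`, `"technician"`, `"pathologist"`, `"molecular_biologist"`,
#'   `"bioinformatician"`, `"board_member"`.
#' @param minutes_per_sample,minutes_per_run Non-negative personnel minutes.
#' @param material_per_sample,material_per_run Non-negative euros.
#' @param equipment_annual Non-negative euros per year.
#' @return A one-row data frame; rows from several calls can be `rbind`-ed
#'   into a schedule for [aggregate_panel_costs()].
#' @export
activity_step <- function(label, role,
                          minutes_per_sample = 0, minutes_per_run = 0,
                          material_per_sample = 0, material_per_run = 0,
                          equipment_annual = 0) {
  role <- match.arg(role, personnel_roles())
  fields <- c(minutes_per_sample = minutes_per_sample,
              minutes_per_run = minutes_per_run,
              material_per_sample = material_per_sample,
              material_per_run = material_per_run,
              equipment_annual = equipment_annual)
  for (nm in names(fields)) check_number(fields[[nm]], nm, min = 0)
  if (all(fields == 0)) {
    stop("activity step '", label, "' contributes to no cost field",
         call. = FALSE)
  }
  data.frame(label = label, role = role,
             minutes_per_sample = minutes_per_sample,
             minutes_per_run = minutes_per_run,
             material_per_sample = material_per_sample,
             material_per_run = material_per_run,
             equipment_annual = equipment_annual,
             stringsAsFactors = FALSE)
}

personnel_roles <- function() {
  c("secretary", "technician", "pathologist", "molecular_biologist",
    "bioinformatician", "board_member")
}

#' Aggregate an activity schedule into a panel cost decomposition
#'
#' Sums personnel minutes (priced at the per-role rates), material costs and
#' annual equipment costs of an activity schedule into the fixed-yearly /
#' fixed-per-run / variable-per-sample decomposition of one panel on one
#' platform. Values are unrounded euros.
#'
#' @param steps Data frame of activity steps (see [activity_step()] and
#'   [load_activity_schedule()]).
#' @param rates Named numeric vector of personnel rates in euros per minute,
#'   one entry per role appearing in `steps`.
#' @param panel,platform Optional labels stored on the result.
#' @param max_samples_per_run Capacity of a run for this panel/platform
#'   combination (default 48).
#' @return A `panel_cost_spec` object; see [panel_cost_spec()].
#' @export
aggregate_panel_costs <- function(steps, rates, panel = NA_character_,
                                  platform = NA_character_,
                                  max_samples_per_run = 48L) {
  if (nrow(steps) == 0L) {
    return(panel_cost_spec(panel = panel, platform = platform,
                           fixed_yearly = 0, fixed_per_run_personnel = 0,
                           fixed_per_run_material = 0,
                           variable_per_sample_personnel = 0,
                           variable_per_sample_material = 0,
                           max_samples_per_run = max_samples_per_run))
  }
  num_cols <- c("minutes_per_sample", "minutes_per_run",
                "material_per_sample", "material_per_run", "equipment_annual")
  for (col in num_cols) {
    if (any(steps[[col]] < 0)) {
      stop("negative value in column `", col, "`", call. = FALSE)
    }
  }
  missing_rate <- setdiff(unique(steps$role), names(rates))
  if (length(missing_rate) > 0L) {
    stop("no personnel rate configured for role(s): ",
         paste(missing_rate, collapse = ", "), call. = FALSE)
  }
  if (any(rates[unique(steps$role)] <= 0)) {
    stop("personnel rates must be positive", call. = FALSE)
  }
  per_min <- unname(rates[steps$role])
  panel_cost_spec(
    panel = panel, platform = platform,
    fixed_yearly = sum(steps$equipment_annual),
    fixed_per_run_personnel = sum(steps$minutes_per_run * per_min),
    fixed_per_run_material = sum(steps$material_per_run),
    variable_per_sample_personnel = sum(steps$minutes_per_sample * per_min),
    variable_per_sample_material = sum(steps$material_per_sample),
    max_samples_per_run = max_samples_per_run
  )
}

#' Panel cost decomposition
#'
#' The fixed-yearly / fixed-per-run / variable-per-sample cost decomposition
#' of one panel on one platform, split into personnel and material where the
#' split exists. Usually built by [aggregate_panel_costs()] or loaded via
#' [panel_spec()].
#'
#' @param panel,platform Labels (e.g. `"small_tgp"`, `"miseq"`).
#' @param fixed_yearly Euros per year (equipment).
#' @param fixed_per_run_personnel,fixed_per_run_material Euros per run.
#' @param variable_per_sample_personnel,variable_per_sample_material Euros
#'   per sample.
#' @param max_samples_per_run Positive integer run capacity.
#' @return An object of class `panel_cost_spec`.
#' @export
panel_cost_spec <- function(panel = NA_character_, platform = NA_character_,
                            fixed_yearly = 0,
                            fixed_per_run_personnel = 0,
                            fixed_per_run_material = 0,
                            variable_per_sample_personnel = 0,
                            variable_per_sample_material = 0,
                            max_samples_per_run = 48L) {
  money <- c(fixed_yearly = fixed_yearly,
             fixed_per_run_personnel = fixed_per_run_personnel,
             fixed_per_run_material = fixed_per_run_material,
             variable_per_sample_personnel = variable_per_sample_personnel,
             variable_per_sample_material = variable_per_sample_material)
  for (nm in names(money)) check_number(money[[nm]], nm, min = 0)
  check_number(max_samples_per_run, "max_samples_per_run", min = 1)
  structure(
    list(panel = panel, platform = platform,
         fixed_yearly = fixed_yearly,
         fixed_per_run_personnel = fixed_per_run_personnel,
         fixed_per_run_material = fixed_per_run_material,
         variable_per_sample_personnel = variable_per_sample_personnel,
         variable_per_sample_material = variable_per_sample_material,
         max_samples_per_run = as.integer(max_samples_per_run)),
    class = "panel_cost_spec"
  )
}

#' @export
print.panel_cost_spec <- function(x, ...) {
  cat(sprintf("<panel_cost_spec> %s on %s (max %d samples/run)\n",
              x$panel, x$platform, x$max_samples_per_run))
  cat(sprintf("  fixed yearly (equipment)   EUR %s/year\n",
              format(round_euro(x$fixed_yearly), big.mark = ",")))
  cat(sprintf("  fixed per run              EUR %s personnel + EUR %s material\n",
              round_euro(x$fixed_per_run_personnel),
              format(round_euro(x$fixed_per_run_material), big.mark = ",")))
  cat(sprintf("  variable per sample        EUR %s personnel + EUR %s material\n",
              round_euro(x$variable_per_sample_personnel),
              round_euro(x$variable_per_sample_material)))
  invisible(x)
}

#' Number of control samples in a run
#'
#' Runs with at most eight booked samples carry one quality-control sample;
#' larger runs carry two.
#'
#' @param patient_samples Number of patient samples booked on the run
#'   (positive integer).
#' @return Integer, 1 or 2.
#' @examples
#' n_controls(8)  # 1
#' n_controls(9)  # 2
#' @export
n_controls <- function(patient_samples) {
  check_number(patient_samples, "patient_samples", min = 1)
  if (patient_samples != round(patient_samples)) {
    stop("`patient_samples` must be a whole number", call. = FALSE)
  }
  if (patient_samples <= 8) 1L else 2L
}

#' Construct a run plan
#'
#' Throughput assumptions under which a panel cost decomposition is turned
#' into a cost per patient sample.
#'
#' @param samples_per_run Patient samples booked per run (positive integer).
#' @param runs_per_week Runs executed per week (positive, may be fractional).
#' @param fill_fraction Average fraction of booked capacity actually used,
#'   in (0, 1].
#' @param weeks_per_year Operating weeks per year (default 52).
#' @param overhead_fraction Institutional overhead applied multiplicatively
#'   to the full per-sample cost (default 0.30).
#' @return An object of class `run_plan`.
#' @export
run_plan <- function(samples_per_run, runs_per_week = 1, fill_fraction = 1,
                     weeks_per_year = 52L, overhead_fraction = 0.30) {
  check_number(samples_per_run, "samples_per_run", min = 1)
  if (samples_per_run != round(samples_per_run)) {
    stop("`samples_per_run` must be a whole number", call. = FALSE)
  }
  check_number(runs_per_week, "runs_per_week", min = 0, strict_min = TRUE)
  check_number(fill_fraction, "fill_fraction", min = 0, max = 1,
               strict_min = TRUE)
  check_number(weeks_per_year, "weeks_per_year", min = 1)
  check_number(overhead_fraction, "overhead_fraction", min = 0)
  structure(list(samples_per_run = as.integer(samples_per_run),
                 runs_per_week = runs_per_week,
                 fill_fraction = fill_fraction,
                 weeks_per_year = as.integer(weeks_per_year),
                 overhead_fraction = overhead_fraction),
            class = "run_plan")
}

#' The reference run plan
#'
#' 24 samples booked per run, one run per week, 85% of the run filled on
#' average, 30% overhead — the operating point at which the per-sample costs
#' of the packaged panels are quoted.
#'
#' @return A [run_plan()].
#' @export
base_run_plan <- function() run_plan(24L, runs_per_week = 1, fill_fraction = 0.85)

#' Cost per patient sample under a run plan
#'
#' Allocates the yearly fixed costs over the runs of a year, adds the fixed
#' per-run costs and the variable costs of the effective patient samples plus
#' the run's control samples, divides by the effective patient samples and
#' applies overhead. All composition is unrounded; use [round_euro()] (or the
#' print method) for the reported whole-euro figure.
#'
#' @param spec A [panel_cost_spec()].
#' @param plan A [run_plan()]; `plan$samples_per_run` must not exceed
#'   `spec$max_samples_per_run`.
#' @param controls Optional override of the number of control samples; by
#'   default [n_controls()] of the booked run size.
#' @return An object of class `cost_breakdown` with unrounded fields
#'   `cost_per_patient_sample`, `fixed_share`, `variable_share`,
#'   `overhead_share`, `n_patient_samples_effective`, `n_controls`.
#' @examples
#' spec <- panel_spec("small_tgp", "miseq")
#' cost_per_sample(spec, base_run_plan())
#' @export
cost_per_sample <- function(spec, plan, controls = NULL) {
  stopifnot(inherits(spec, "panel_cost_spec"), inherits(plan, "run_plan"))
  if (plan$samples_per_run > spec$max_samples_per_run) {
    stop(sprintf("run of %d samples exceeds the %s/%s capacity of %d",
                 plan$samples_per_run, spec$panel, spec$platform,
                 spec$max_samples_per_run), call. = FALSE)
  }
  ctrl <- if (is.null(controls)) n_controls(plan$samples_per_run) else {
    check_number(controls, "controls", min = 0)
    as.integer(controls)
  }
  n_eff <- plan$fill_fraction * plan$samples_per_run
  runs_per_year <- plan$weeks_per_year * plan$runs_per_week
  fixed_run <- spec$fixed_yearly / runs_per_year +
    spec$fixed_per_run_personnel + spec$fixed_per_run_material
  variable_unit <- spec$variable_per_sample_personnel +
    spec$variable_per_sample_material
  fixed_share <- fixed_run / n_eff
  variable_share <- (n_eff + ctrl) * variable_unit / n_eff
  overhead_share <- plan$overhead_fraction * (fixed_share + variable_share)
  structure(
    list(cost_per_patient_sample = fixed_share + variable_share + overhead_share,
         fixed_share = fixed_share,
         variable_share = variable_share,
         overhead_share = overhead_share,
         n_patient_samples_effective = n_eff,
         n_controls = ctrl,
         panel = spec$panel, platform = spec$platform),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s on %s\n", x$panel, x$platform))
  cat(sprintf("  cost per patient sample  EUR %s\n",
              format(round_euro(x$cost_per_patient_sample), big.mark = ",")))
  cat(sprintf("    fixed share            EUR %.2f\n", x$fixed_share))
  cat(sprintf("    variable share         EUR %.2f\n", x$variable_share))
  cat(sprintf("    overhead share         EUR %.2f\n", x$overhead_share))
  cat(sprintf("  effective patient samples %.2f, controls %d\n",
              x$n_patient_samples_effective, x$n_controls))
  invisible(x)
}

#' Cost-per-sample curve over run sizes
#'
#' Evaluates [cost_per_sample()] over a series of run sizes with the fill
#' fraction forced to 1 (complete runs), the convention under which the
#' minimum achievable per-sample cost of a panel is quoted.
#'
#' @param spec A [panel_cost_spec()].
#' @param plan_template A [run_plan()] providing runs-per-week, weeks and
#'   overhead; its `samples_per_run` and `fill_fraction` are ignored.
#' @param sample_counts Positive integers, each at most
#'   `spec$max_samples_per_run`.
#' @return Data frame with columns `samples_per_run` and `cost_per_sample`
#'   (unrounded euros).
#' @export
cost_curve <- function(spec, plan_template = run_plan(1L),
                       sample_counts = seq_len(spec$max_samples_per_run)) {
  costs <- vapply(sample_counts, function(k) {
    plan <- run_plan(k,
                     runs_per_week = plan_template$runs_per_week,
                     fill_fraction = 1,
                     weeks_per_year = plan_template$weeks_per_year,
                     overhead_fraction = plan_template$overhead_fraction)
    cost_per_sample(spec, plan)$cost_per_patient_sample
  }, numeric(1))
  data.frame(samples_per_run = as.integer(sample_counts),
             cost_per_sample = costs)
}
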