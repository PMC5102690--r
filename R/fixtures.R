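# Loaders for the packaged configuration fixtures: personnel rates, activity
# schedules, the national BIA scenario file and the case-study cohort
# profiles. All fixtures are plain YAML under inst/extdata.

#' Load the packaged personnel rates
#'
#' Per-role personnel rates in euros per direct productive minute. The rates
#' are calibrated constants: per-role figures are not public, so they were
#' solved once so that the packaged activity schedules aggregate to the
#' published personnel cost decomposition of both panels (see the methods
#' vignette).
#'
#' @param path Path to a YAML file mapping role to euros/minute; defaults to
#'   the packaged fixture.
#' @return Named numeric vector.
#' @export
load_personnel_rates <- function(path = panelcost_extdata("personnel_rates.yaml")) {
  raw <- yaml::read_yaml(path)
  rates <- unlist(raw)
  if (any(rates <= 0)) stop("personnel rates must be positive", call. = FALSE)
  rates
}

#' Load a packaged activity schedule
#'
#' Reads the activity schedule of one panel, resolving platform-dependent
#' fields (sequencer depreciation, run consumables) for the requested
#' platform.
#'
#' @param panel `"small_tgp"` or `"medium_tgp"`.
#' @param platform `"miseq"` or `"hiseq"`.
#' @param path Schedule YAML; defaults to the packaged fixture.
#' @return Data frame of activity steps with attributes `panel`, `platform`
#'   and `max_samples_per_run`.
#' @export
load_activity_schedule <- function(panel = c("small_tgp", "medium_tgp"),
                                   platform = c("miseq", "hiseq"),
                                   path = panelcost_extdata("activity_schedules.yaml")) {
  panel <- match.arg(panel)
  platform <- match.arg(platform)
  raw <- yaml::read_yaml(path)
  if (is.null(raw[[panel]])) stop("no schedule for panel ", panel, call. = FALSE)
  sched <- raw[[panel]]
  resolve <- function(x, default = 0) {
    if (is.null(x)) return(default)
    if (is.list(x)) {
      if (is.null(x[[platform]])) {
        stop("platform-dependent field lacks an entry for ", platform,
             call. = FALSE)
      }
      return(x[[platform]])
    }
    x
  }
  steps <- do.call(rbind, lapply(sched$steps, function(s) {
    activity_step(label = s$label, role = s$role,
                  minutes_per_sample = resolve(s$minutes_per_sample),
                  minutes_per_run = resolve(s$minutes_per_run),
                  material_per_sample = resolve(s$material_per_sample),
                  material_per_run = resolve(s$material_per_run),
                  equipment_annual = resolve(s$equipment_annual))
  }))
  attr(steps, "panel") <- panel
  attr(steps, "platform") <- platform
  attr(steps, "max_samples_per_run") <- resolve(sched$max_samples_per_run, 48L)
  steps
}

#' Packaged panel cost decomposition
#'
#' Convenience wrapper: loads the packaged activity schedule and personnel
#' rates for one panel/platform combination and aggregates them with
#' [aggregate_panel_costs()].
#'
#' @inheritParams load_activity_schedule
#' @return A [panel_cost_spec()].
#' @examples
#' panel_spec("small_tgp", "miseq")
#' @export
panel_spec <- function(panel = c("small_tgp", "medium_tgp"),
                       platform = c("miseq", "hiseq")) {
  panel <- match.arg(panel)
  platform <- match.arg(platform)
  steps <- load_activity_schedule(panel, platform)
  aggregate_panel_costs(steps, load_personnel_rates(),
                        panel = panel, platform = platform,
                        max_samples_per_run = attr(steps, "max_samples_per_run"))
}

#' Load and validate a BIA scenario configuration
#'
#' Reads a scenario file (catalog, populations, scenarios per time frame,
#' indication and hospital stratum) and validates it with
#' [validate_config()].
#'
#' @param path YAML configuration file.
#' @return A validated `bia_config` object.
#' @export
load_bia_config <- function(path) {
  validate_config(yaml::read_yaml(path), source = path)
}

#' The packaged national BIA configuration
#'
#' The canonical configuration encodes the national scenario grid for the
#' Dutch stage-IV NSCLC and melanoma populations over the 2012/2015/2020
#' time frames. The `"alt559"` variant differs only in the NSCLC
#' current-peripheral cell, which follows the published summary table (559)
#' instead of the running text (590); see the methods vignette.
#'
#' @param variant `"canonical"` (default) or `"alt559"`.
#' @return A validated `bia_config` object.
#' @export
default_bia_config <- function(variant = c("canonical", "alt559")) {
  variant <- match.arg(variant)
  file <- switch(variant,
                 canonical = "netherlands_bia.yaml",
                 alt559 = "netherlands_bia_alt559.yaml")
  load_bia_config(panelcost_extdata(file))
}

#' The packaged unit-cost test catalog
#'
#' @param config A `bia_config`; defaults to the packaged configuration.
#' @return A `test_catalog` data frame (columns `test`, `unit_cost`).
#' @export
default_catalog <- function(config = default_bia_config()) {
  config$catalog
}

#' Packaged case-study cohort profile
#'
#' Cohort profiles for the four institutional case-study arms, parameterised
#' from the published arm summaries (test counts, mutation counts, treatment
#' category counts); the test mixes are package choices documented in the
#' fixture file and the methods vignette.
#'
#' @param name One of `"nsclc_before"`, `"nsclc_after"`, `"melanoma_before"`,
#'   `"melanoma_after"`.
#' @return A [cohort_profile()].
#' @export
table_profile <- function(name = c("nsclc_before", "nsclc_after",
                                   "melanoma_before", "melanoma_after")) {
  name <- match.arg(name)
  raw <- yaml::read_yaml(panelcost_extdata("cohort_profiles.yaml"))[[name]]
  counts <- unlist(raw$categories)
  cohort_profile(
    indication = raw$indication,
    period = raw$period,
    n_patients = raw$n_patients,
    tests_mean = raw$tests_per_patient$mean,
    tests_min = raw$tests_per_patient$min,
    tests_max = raw$tests_per_patient$max,
    test_mix = unlist(raw$test_mix),
    mutation_mean = raw$mutations_per_patient$mean,
    mutation_min = raw$mutations_per_patient$min,
    mutation_max = raw$mutations_per_patient$max,
    category_probs = counts / raw$n_patients
  )
}
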