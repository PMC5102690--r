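# One-way (deterministic) sensitivity analysis with tornado-ordered output.
# A model is a function of a named list of parameter overrides; one_way()
# evaluates it at the low and high end of one parameter with everything else
# at base, and tornado() stacks the resulting ranges sorted by width.

#' Define a sensitivity parameter
#'
#' @param name Parameter name; must match an override key understood by the
#'   model it is applied to.
#' @param base_value Base value of the parameter.
#' @param low,high Extremes to evaluate; `low <= base_value <= high`.
#' @return A `sensitivity_param` list.
#' @export
sensitivity_param <- function(name, base_value, low, high) {
  check_number(base_value, "base_value")
  check_number(low, "low")
  check_number(high, "high")
  if (low > base_value || base_value > high) {
    stop("`low <= base_value <= high` violated for parameter ", name,
         call. = FALSE)
  }
  structure(list(name = name, base_value = base_value, low = low, high = high),
            class = "sensitivity_param")
}

#' Relative-range sensitivity parameter
#'
#' Convenience constructor for the conventional symmetric relative range
#' (default ±20%).
#'
#' @param name Parameter name.
#' @param base_value Base value.
#' @param rel_range Relative half-width (default 0.2).
#' @return A [sensitivity_param()].
#' @export
rel_param <- function(name, base_value, rel_range = 0.2) {
  sensitivity_param(name, base_value,
                    low = base_value * (1 - rel_range),
                    high = base_value * (1 + rel_range))
}

#' One-way sensitivity of a model to one parameter
#'
#' Evaluates the model at the parameter's low and high extreme, all other
#' parameters at base.
#'
#' @param model Function taking a named list of parameter overrides and
#'   returning a numeric outcome.
#' @param param A [sensitivity_param()].
#' @return One-row data frame (`param`, `outcome_at_low`, `outcome_at_high`,
#'   `width`), a tornado entry.
#' @export
one_way <- function(model, param) {
  stopifnot(inherits(param, "sensitivity_param"))
  eval_at <- function(value) {
    overrides <- stats::setNames(list(value), param$name)
    tryCatch(model(overrides), error = function(e) {
      stop(sprintf("model failed at %s = %g: %s",
                   param$name, value, conditionMessage(e)), call. = FALSE)
    })
  }
  lo <- eval_at(param$low)
  hi <- eval_at(param$high)
  data.frame(param = param$name,
             outcome_at_low = lo, outcome_at_high = hi,
             width = abs(hi - lo),
             stringsAsFactors = FALSE)
}

#' Tornado table: one-way analyses sorted by width
#'
#' @param model Outcome function as in [one_way()].
#' @param params List of [sensitivity_param()]s (at least one).
#' @return Data frame of tornado entries sorted by descending width; ties
#'   keep their input order.
#' @export
tornado <- function(model, params) {
  if (length(params) < 1L) stop("at least one parameter required", call. = FALSE)
  entries <- do.call(rbind, lapply(params, function(p) one_way(model, p)))
  entries <- entries[order(-entries$width), , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

#' Budget-impact model of the future scenario
#'
#' Builds the outcome function "population budget impact of the future frame
#' relative to the current frame" for one indication, with the future-frame
#' prices and the specialised-care share exposed as perturbable parameters.
#' Perturbations apply to the future time frame only; the current frame keeps
#' its base costs. Understood override names: `tgp_price` (peripheral panel
#' price), `wgs_price` (specialised WGS price) and `specialised_share`
#' (absolute share; the peripheral share is renormalised to keep the sum at
#' one).
#'
#' @param config A `bia_config`.
#' @param indication `"nsclc"` or `"melanoma"`.
#' @return Function of a named override list returning euros/year.
#' @examples
#' m <- future_bia_model(default_bia_config(), "nsclc")
#' m()                            # base budget impact
#' m(list(tgp_price = 727.2))    # panel price +20%
#' @export
future_bia_model <- function(config, indication) {
  cells <- scenario_cells(config, "future_2020", indication)
  strata <- vapply(cells, `[[`, character(1), "stratum")
  base_cost <- function(cell) {
    cell$printed_cost %||% bundle_cost(cell$bundle, config$catalog)
  }
  base_tgp <- base_cost(cells[[which(strata == "peripheral")]])
  base_wgs <- base_cost(cells[[which(strata == "specialised")]])
  base_share <- cells[[which(strata == "specialised")]]$patient_share
  patients_future <- config$populations[[indication]][["future_2020"]]
  pop_current <- population_cost(config, "current_2015", indication)
  function(overrides = list()) {
    unknown <- setdiff(names(overrides),
                       c("tgp_price", "wgs_price", "specialised_share"))
    if (length(unknown) > 0L) {
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    tgp <- overrides$tgp_price %||% base_tgp
    wgs <- overrides$wgs_price %||% base_wgs
    share <- overrides$specialised_share %||% base_share
    if (share < 0 || share > 1) {
      stop("`specialised_share` must lie in [0, 1]", call. = FALSE)
    }
    per_patient <- (1 - share) * tgp + share * wgs
    patients_future * per_patient - pop_current
  }
}

#' Default parameter set for the future budget-impact tornado
#'
#' The three future-scenario parameters at the conventional symmetric
#' relative range: panel price, WGS price and the specialised-care share
#' (perturbed relatively, e.g. 70% to 56%/84%).
#'
#' @param config A `bia_config`.
#' @param indication `"nsclc"` or `"melanoma"`.
#' @param rel_range Relative half-width (default from the configuration,
#'   falling back to 0.2).
#' @return List of [sensitivity_param()]s.
#' @export
future_bia_params <- function(config, indication, rel_range = NULL) {
  rel_range <- rel_range %||% config$sensitivity$relative_range %||% 0.2
  cells <- scenario_cells(config, "future_2020", indication)
  strata <- vapply(cells, `[[`, character(1), "stratum")
  base_cost <- function(cell) {
    cell$printed_cost %||% bundle_cost(cell$bundle, config$catalog)
  }
  list(
    rel_param("tgp_price", base_cost(cells[[which(strata == "peripheral")]]),
              rel_range),
    rel_param("wgs_price", base_cost(cells[[which(strata == "specialised")]]),
              rel_range),
    rel_param("specialised_share",
              cells[[which(strata == "specialised")]]$patient_share, rel_range)
  )
}

#' Sensitivity of the current specialised test cost
#'
#' One-way sensitivity of the per-patient test cost in the current
#' specialised setting: small-panel cost per sample under the run plan plus
#' the required additional single-gene tests. Perturbable parameters:
#' `samples_per_run`, `runs_per_week`, `fill_fraction` and
#' `n_additional_tests` (whole tests, priced from the catalog in the order of
#' `additional_tests`).
#'
#' @param params List of [sensitivity_param()]s over the four parameter
#'   names; defaults to realistic operating ranges (run size 4–48, 0.5–2
#'   runs/week, fill 0.5–1, 0–3 additional tests).
#' @param spec A [panel_cost_spec()]; defaults to the packaged small panel on
#'   the benchtop sequencer.
#' @param catalog A [test_catalog()].
#' @param additional_tests Character vector of catalog entries required
#'   besides the panel at base (default two sequence-analysis tests and one
#'   FISH).
#' @param base Named list with the base run plan (`samples_per_run`,
#'   `runs_per_week`, `fill_fraction`).
#' @return Tornado-ordered data frame as from [tornado()], with the base
#'   outcome attached as attribute `base_outcome`.
#' @export
current_cost_sensitivity <- function(params = NULL,
                                     spec = panel_spec("small_tgp", "miseq"),
                                     catalog = default_catalog(),
                                     additional_tests = c("single_gene_sanger",
                                                          "single_gene_sanger",
                                                          "single_gene_fish"),
                                     base = list(samples_per_run = 24L,
                                                 runs_per_week = 1,
                                                 fill_fraction = 0.85)) {
  prices <- catalog_price(catalog, additional_tests)
  model <- function(overrides = list()) {
    p <- utils::modifyList(c(base, list(n_additional_tests = length(prices))),
                           overrides)
    plan <- run_plan(p$samples_per_run, runs_per_week = p$runs_per_week,
                     fill_fraction = p$fill_fraction)
    n_add <- p$n_additional_tests
    if (n_add < 0 || n_add > length(prices) || n_add != round(n_add)) {
      stop("`n_additional_tests` must be a whole number within the configured list",
           call. = FALSE)
    }
    cost_per_sample(spec, plan)$cost_per_patient_sample +
      sum(prices[seq_len(n_add)])
  }
  if (is.null(params)) {
    params <- list(
      sensitivity_param("samples_per_run", base$samples_per_run, 4,
                        spec$max_samples_per_run),
      sensitivity_param("runs_per_week", base$runs_per_week, 0.5, 2),
      sensitivity_param("fill_fraction", base$fill_fraction, 0.5, 1),
      sensitivity_param("n_additional_tests", length(prices), 0, length(prices))
    )
  }
  out <- tornado(model, params)
  attr(out, "base_outcome") <- model()
  out
}
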