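# Activity-based costing engine: schedule aggregation, control-sample rule,
# cost per sample under a run plan, and the cost curve.

test_that("packaged schedules aggregate to the published panel decomposition", {
  rates <- load_personnel_rates()
  steps <- load_activity_schedule("small_tgp", "miseq")
  spec <- aggregate_panel_costs(steps, rates, panel = "small_tgp",
                                platform = "miseq")
  expect_equal(spec$fixed_per_run_personnel, 347, tolerance = 0.005)
  expect_equal(spec$variable_per_sample_personnel, 121, tolerance = 0.005)
  expect_equal(spec$fixed_yearly, 96589)
  expect_equal(spec$fixed_per_run_material, 1198)
  expect_equal(spec$variable_per_sample_material, 155)

  med <- panel_spec("medium_tgp", "hiseq")
  expect_equal(med$fixed_per_run_personnel, 840, tolerance = 0.005)
  expect_equal(med$variable_per_sample_personnel, 153, tolerance = 0.005)
  expect_equal(med$fixed_yearly, 264207, tolerance = 1e-4)
  expect_equal(med$fixed_per_run_material, 5435)
  expect_equal(med$variable_per_sample_material, 136)
  expect_identical(panel_spec("medium_tgp", "miseq")$max_samples_per_run, 4L)
})

test_that("aggregation is linear: duplicating every step doubles every field", {
  rates <- load_personnel_rates()
  steps <- load_activity_schedule("small_tgp", "hiseq")
  once <- aggregate_panel_costs(steps, rates)
  twice <- aggregate_panel_costs(rbind(steps, steps), rates)
  for (field in c("fixed_yearly", "fixed_per_run_personnel",
                  "fixed_per_run_material", "variable_per_sample_personnel",
                  "variable_per_sample_material")) {
    expect_equal(twice[[field]], 2 * once[[field]])
  }
})

test_that("aggregation validates its inputs", {
  rates <- load_personnel_rates()
  steps <- load_activity_schedule("small_tgp", "miseq")
  empty <- aggregate_panel_costs(steps[0, ], rates)
  expect_equal(empty$fixed_yearly, 0)
  expect_equal(empty$variable_per_sample_personnel, 0)

  expect_error(aggregate_panel_costs(steps, rates[names(rates) != "technician"]),
               "technician")
  bad <- steps
  bad$minutes_per_sample[2] <- -1
  expect_error(aggregate_panel_costs(bad, rates), "negative")
  expect_error(activity_step("idle", "technician"), "no cost field")
})

test_that("control sample count follows the run-size rule", {
  expect_identical(n_controls(1), 1L)
  expect_identical(n_controls(8), 1L)
  expect_identical(n_controls(9), 2L)
  expect_identical(n_controls(48), 2L)
  expect_error(n_controls(0), ">= 1")
})

test_that("cost per sample reproduces the published operating points", {
  base <- base_run_plan()
  small_miseq <- cost_per_sample(panel_spec("small_tgp", "miseq"), base)
  expect_equal(small_miseq$cost_per_patient_sample, 606, tolerance = 0.02)
  expect_equal(cost_per_sample(panel_spec("small_tgp", "hiseq"),
                               base)$cost_per_patient_sample,
               956, tolerance = 0.02)
  expect_equal(cost_per_sample(panel_spec("medium_tgp", "hiseq"),
                               base)$cost_per_patient_sample,
               1137, tolerance = 0.02)
  # maximum cost at the smallest run, 85% filled
  expect_equal(cost_per_sample(panel_spec("small_tgp", "miseq"),
                               run_plan(4, 1, 0.85))$cost_per_patient_sample,
               1769, tolerance = 0.02)
  # breakdown identity and bookkeeping
  expect_equal(small_miseq$cost_per_patient_sample,
               small_miseq$fixed_share + small_miseq$variable_share +
                 small_miseq$overhead_share)
  expect_equal(small_miseq$n_patient_samples_effective, 0.85 * 24)
  expect_identical(small_miseq$n_controls, 2L)
})

test_that("with no fixed costs and no controls the cost is overheaded variable cost", {
  spec <- panel_cost_spec(variable_per_sample_personnel = 100,
                          variable_per_sample_material = 50)
  got <- cost_per_sample(spec, run_plan(10, 1, 1), controls = 0)
  expect_equal(got$cost_per_patient_sample, 150 * 1.3)
})

test_that("capacity and plan validation errors are raised", {
  med_miseq <- panel_spec("medium_tgp", "miseq")
  expect_error(cost_per_sample(med_miseq, run_plan(24, 1, 0.85)), "capacity|exceeds")
  expect_error(run_plan(24, 1, 0), "fill_fraction")
  expect_error(run_plan(24, 1, 1.2), "fill_fraction")
})

test_that("cost per sample is strictly decreasing in run size, fill and run frequency", {
  spec <- panel_spec("small_tgp", "miseq")
  cps <- function(samples, runs = 1, fill = 0.85) {
    cost_per_sample(spec, run_plan(samples, runs, fill))$cost_per_patient_sample
  }
  by_samples <- vapply(c(9, 16, 24, 32, 48), cps, numeric(1))
  expect_true(all(diff(by_samples) < 0))
  by_fill <- vapply(c(0.5, 0.7, 0.85, 1), function(f) cps(24, fill = f),
                    numeric(1))
  expect_true(all(diff(by_fill) < 0))
  by_runs <- vapply(c(0.5, 1, 2, 4), function(r) cps(24, runs = r), numeric(1))
  expect_true(all(diff(by_runs) < 0))
})

test_that("cost per sample is homogeneous in the monetary fields", {
  spec <- panel_spec("small_tgp", "hiseq")
  lambda <- 3.7
  scaled <- panel_cost_spec(
    fixed_yearly = lambda * spec$fixed_yearly,
    fixed_per_run_personnel = lambda * spec$fixed_per_run_personnel,
    fixed_per_run_material = lambda * spec$fixed_per_run_material,
    variable_per_sample_personnel = lambda * spec$variable_per_sample_personnel,
    variable_per_sample_material = lambda * spec$variable_per_sample_material)
  plan <- run_plan(17, 1.5, 0.9)
  expect_equal(cost_per_sample(scaled, plan)$cost_per_patient_sample,
               lambda * cost_per_sample(spec, plan)$cost_per_patient_sample)
})

test_that("as fixed costs vanish the cost approaches the closed-form limit", {
  plan <- run_plan(12, 1, 0.8)
  limit <- panel_cost_spec(variable_per_sample_personnel = 121,
                           variable_per_sample_material = 155)
  n_p <- 0.8 * 12
  closed_form <- 1.3 * 276 * (n_p + 2) / n_p
  expect_equal(cost_per_sample(limit, plan)$cost_per_patient_sample,
               closed_form)
})

test_that("cost curve matches point-wise evaluation and is monotone", {
  spec <- panel_spec("small_tgp", "miseq")
  curve <- cost_curve(spec, sample_counts = 4:48)
  # minimum cost at a complete 48-sample run
  expect_equal(curve$cost_per_sample[curve$samples_per_run == 48],
               465, tolerance = 0.02)
  # brute force every point independently and check ordering
  brute <- vapply(4:48, function(k) {
    cost_per_sample(spec, run_plan(k, 1, 1))$cost_per_patient_sample
  }, numeric(1))
  expect_equal(curve$cost_per_sample, brute)
  expect_true(all(diff(brute) < 0))
  # determinism: repeated counts give identical costs
  rep_curve <- cost_curve(spec, sample_counts = c(24, 24))
  expect_identical(rep_curve$cost_per_sample[1], rep_curve$cost_per_sample[2])
})

test_that("euro rounding is half away from zero", {
  expect_identical(round_euro(c(0.5, 1.5, -0.5, -13.8, 537.4)),
                   c(1, 2, -1, -14, 537))
})
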