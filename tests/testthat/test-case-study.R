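# Case-study pipeline: period summaries, rule-based test selection,
# before/after comparison, annualisation and institutional budget impact.

catalog <- default_catalog()

test_that("period summary aggregates per-patient measures and categories", {
  records <- rbind(
    make_record("p1", "nsclc", "before", c("single_gene_sanger", "single_gene_fish"),
                mutations = 1, true_cats = "ema_tt_available"),
    make_record("p2", "nsclc", "before", "small_tgp", mutations = 0),
    make_record("p3", "nsclc", "before",
                c("single_gene_sanger", "single_gene_sanger", "multigene_panel"),
                mutations = 2, true_cats = c("ema_tt_available", "started_ema_tt")))
  s <- summarize_period(records, catalog)
  expect_identical(s$n_patients, 3L)
  stats <- s$stats
  costs <- c(295 + 309, 606, 295 + 295 + 500)
  expect_equal(stats$mean[stats$variable == "cost_per_patient"], mean(costs))
  expect_equal(stats$min[stats$variable == "cost_per_patient"], min(costs))
  expect_equal(stats$max[stats$variable == "tests_per_patient"], 3)
  expect_equal(stats$mean[stats$variable == "cost_per_test"],
               mean(costs / c(2, 1, 3)))
  cc <- s$category_counts
  expect_equal(cc$count[cc$category == "ema_tt_available"], 2)
  expect_equal(cc$percent[cc$category == "ema_tt_available"], 200 / 3)
  expect_equal(cc$count[cc$category == "started_mab"], 0)
  expect_equal(cc$percent[cc$category == "started_mab"], 0)
  # min <= mean <= max throughout
  expect_true(all(stats$min <= stats$mean & stats$mean <= stats$max))
})

test_that("one patient with one test gives a degenerate summary", {
  s <- summarize_period(make_record("p1", "melanoma", "before",
                                    "single_gene_sanger"), catalog)
  stats <- s$stats
  row <- stats[stats$variable == "cost_per_patient", ]
  expect_equal(unlist(row[c("mean", "min", "max")], use.names = FALSE),
               c(295, 295, 295))
})

test_that("summary is permutation-invariant and validates its input", {
  cohort <- generate_cohort(table_profile("melanoma_after"), seed = 3)
  shuffled <- cohort[sample(nrow(cohort)), ]
  expect_equal(summarize_period(cohort, catalog)$stats,
               summarize_period(shuffled, catalog)$stats)
  mixed <- cohort
  mixed$period[1] <- "before"
  expect_error(summarize_period(mixed, catalog), "one indication and one period")
  unknown <- cohort
  unknown$tests[1] <- "karyotype"
  expect_error(summarize_period(unknown, catalog), "karyotype")
})

test_that("statistical test selection follows the rule", {
  expect_identical(select_test("continuous", TRUE), "t")
  expect_identical(select_test("continuous", FALSE), "mann_whitney")
  expect_identical(select_test("binary", TRUE), "fisher")
  expect_identical(select_test("binary", FALSE), "fisher")
})

test_that("Fisher comparison reproduces the published 2x2 p-value", {
  before <- make_flag_cohort(47, "nsclc", "before", "ema_tt_available", 7)
  after <- make_flag_cohort(53, "nsclc", "after", "ema_tt_available", 6)
  res <- compare_periods(before, after, catalog)
  p <- res$p_value[res$variable == "ema_tt_available"]
  expect_equal(p, 0.767, tolerance = 0.0015)
  expect_false(res$significant[res$variable == "ema_tt_available"])
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    before <- make_flag_cohort(n1, "nsclc", "before", "started_ema_tt", a)
    after <- make_flag_cohort(n2, "nsclc", "after", "started_ema_tt", c)
    res <- compare_periods(before, after, catalog)
    expect_equal(res$p_value[res$variable == "started_ema_tt"],
                 fisher_enumeration_p(a, n1 - a, c, n2 - c),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 for equal proportions", {
  g <- make_flag_cohort(20, "melanoma", "before", "started_mab", 8)
  h <- g; h$period <- "after"
  res <- compare_periods(g, h, catalog)
  expect_equal(res$p_value[res$variable == "started_mab"], 1)
})

test_that("well-separated Gaussian-like groups are declared significant", {
  set.seed(99)
  # mutation-count surrogate: two clearly separated continuous samples
  before <- do.call(rbind, lapply(1:50, function(i)
    make_record(paste0("b", i), "nsclc", "before", "single_gene_sanger",
                mutations = max(0, round(rnorm(1, 0, 1))))))
  after <- do.call(rbind, lapply(1:50, function(i)
    make_record(paste0("a", i), "nsclc", "after", "single_gene_sanger",
                mutations = max(0, round(rnorm(1, 4, 1))))))
  res <- compare_periods(before, after, catalog)
  expect_true(res$significant[res$variable == "mutations_per_patient"])
})

test_that("zero-variance continuous variables are marked degenerate", {
  before <- make_flag_cohort(5, "nsclc", "before", "started_mab", 2)
  after <- make_flag_cohort(6, "nsclc", "after", "started_mab", 3)
  res <- compare_periods(before, after, catalog)
  # every patient has exactly one identical test: cost variables degenerate
  row <- res[res$variable == "cost_per_patient", ]
  expect_true(is.na(row$p_value))
  expect_match(row$note, "degenerate")
  expect_false(row$significant)
})

test_that("single-patient arms degrade gracefully", {
  res <- compare_periods(
    make_record("b1", "nsclc", "before", "single_gene_sanger", mutations = 1),
    make_record("a1", "nsclc", "after", c("small_tgp", "single_gene_fish"),
                mutations = 2),
    catalog)
  expect_true(all(is.na(res$p_value) | (res$p_value >= 0 & res$p_value <= 1)))
})

test_that("annualisation scales the observation window to a year", {
  p47 <- generate_cohort(table_profile("nsclc_before"), 1)
  p53 <- generate_cohort(table_profile("nsclc_after"), 2)
  ann <- annualize(rbind(p47, p53), 3.5, catalog)
  expect_identical(ann$yearly_patients, 343L)
  mel <- rbind(generate_cohort(table_profile("melanoma_before"), 1),
               generate_cohort(table_profile("melanoma_after"), 2))
  expect_identical(annualize(mel, 3.5, catalog)$yearly_patients, 247L)
  # identity window
  twelve <- p47[1:12, ]
  expect_identical(annualize(twelve, 12, catalog)$yearly_patients, 12L)
  # population cost = yearly patients x period mean cost
  mean_before <- mean(vapply(strsplit(p47$tests, ";"), function(t)
    sum(catalog$unit_cost[match(t, catalog$test)]), numeric(1)))
  expect_equal(ann$population_cost_per_period[["before"]], 343 * mean_before)
  expect_error(annualize(p47, 0, catalog), "observation_months")
})

test_that("institutional budget impact reproduces the published case aggregates", {
  # summaries carrying the unrounded means implied by the published
  # population cells (population cost / yearly patients)
  make_summary <- function(indication, period, mean_cost) {
    rec <- make_record("x", indication, period, "single_gene_sanger")
    s <- summarize_period(rec, catalog)
    s$stats$mean[s$stats$variable == "cost_per_patient"] <- mean_cost
    s
  }
  nsclc <- institutional_budget_impact(
    make_summary("nsclc", "before", 268870 / 343),
    make_summary("nsclc", "after", 391368 / 343), 343)
  expect_equal(round_euro(nsclc$per_patient_delta), 357)
  expect_equal(round_euro(nsclc$population_delta), 122498)
  mel <- institutional_budget_impact(
    make_summary("melanoma", "before", 175622 / 247),
    make_summary("melanoma", "after", 172211 / 247), 247)
  expect_equal(round_euro(mel$per_patient_delta), -14)
  expect_equal(round_euro(mel$population_delta), -3411)
  # combined institutional impact across indications
  expect_equal(round_euro(nsclc$population_delta + mel$population_delta),
               119087)
  # equal summaries: zero impact
  s <- make_summary("nsclc", "before", 500)
  s2 <- s; s2$period <- "after"
  zero <- institutional_budget_impact(s, s2, 343)
  expect_equal(zero$per_patient_delta, 0)
})

test_that("patient records survive a CSV round trip byte-identically", {
  cohort <- generate_cohort(table_profile("nsclc_before"), seed = 5)
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_patient_records(cohort, path1)
  back <- read_patient_records(path1)
  expect_equal(back$tests, cohort$tests)
  expect_equal(back$ema_tt_available, cohort$ema_tt_available)
  write_patient_records(back, path2)
  expect_identical(readLines(path1), readLines(path2))
})
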