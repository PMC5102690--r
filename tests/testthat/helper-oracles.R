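# Independent oracles used across the suite.

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration
# (point-probability method: sum the probabilities of all tables no more
# likely than the observed one, with the conventional relative tie
# tolerance). Written from the hypergeometric pmf via log-binomials, not via
# any 2x2-test routine.
fisher_enumeration_p <- function(a, b, c, d) {
  n1 <- a + b   # group 1 size
  m <- a + c    # total positives
  N <- a + b + c + d
  support <- max(0L, m - (N - n1)):min(m, n1)
  logp <- lchoose(m, support) + lchoose(N - m, n1 - support) - lchoose(N, n1)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# brute-force bundle pricing: loop over items, no vectorised shortcut
bundle_cost_bruteforce <- function(items, catalog) {
  total <- 0
  for (i in seq_len(nrow(items))) {
    price <- catalog$unit_cost[catalog$test == items$test[i]]
    total <- total + items$fraction[i] * price
  }
  total
}

# minimal single-patient record for case-study tests
make_record <- function(id, indication, period, tests, mutations = 0,
                        true_cats = character()) {
  rec <- data.frame(patient_id = id, indication = indication, period = period,
                    tests = paste(tests, collapse = ";"),
                    mutation_count = mutations, stringsAsFactors = FALSE)
  for (cat in table_categories()) rec[[cat]] <- cat %in% true_cats
  rec
}

# cohort of n records with given binary category counts, for 2x2 tests
make_flag_cohort <- function(n, indication, period, category, positives) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(sprintf("%s_%s_%d", indication, period, i), indication, period,
                tests = "single_gene_sanger",
                true_cats = if (i <= positives) category else character())
  }))
}
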