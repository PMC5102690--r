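# Synthetic cohort profiles for the four institutional case-study arms
# (before/after NGS implementation, NSCLC and melanoma). Counts-per-patient
# targets (mean, min, max) and binary category counts come from the published
# arm summaries; test mixes are the package's own choice, weighted so the
# per-test cost distribution resembles the published per-test cost summaries.
# Melanoma test-count ranges are not published; realistic ranges consistent
# with the published per-patient cost ranges were chosen once.
nsclc_before:
  indication: nsclc
  period: before
  n_patients: 47
  tests_per_patient: {mean: 2.04, min: 1, max: 4}
  test_mix: {single_gene_sanger: 0.35, single_gene_hrm: 0.05,
             single_gene_fish: 0.20, multigene_panel: 0.40}
  mutations_per_patient: {mean: 0.71, min: 0, max: 3}
  categories:
    ema_tt_available: 7
    trial_tt_available: 11
    started_ema_tt: 2
    included_tt_trial: 4
    tt_option_no_start: 1
    trial_without_tt: 5
    started_mab: 0
    started_mab_trial: 0
    started_radio_chemo: 15
    started_operation: 0
    no_treatment_option: 14
    treated_elsewhere: 6
nsclc_after:
  indication: nsclc
  period: after
  n_patients: 53
  tests_per_patient: {mean: 3.00, min: 1, max: 8}
  test_mix: {small_tgp: 0.22, single_gene_sanger: 0.45, single_gene_hrm: 0.05,
             single_gene_fish: 0.18, multigene_panel: 0.10}
  mutations_per_patient: {mean: 1.06, min: 0, max: 4}
  categories:
    ema_tt_available: 6
    trial_tt_available: 11
    started_ema_tt: 3
    included_tt_trial: 2
    tt_option_no_start: 5
    trial_without_tt: 2
    started_mab: 0
    started_mab_trial: 0
    started_radio_chemo: 20
    started_operation: 0
    no_treatment_option: 13
    treated_elsewhere: 8
melanoma_before:
  indication: melanoma
  period: before
  n_patients: 36
  tests_per_patient: {mean: 2.42, min: 1, max: 6}
  test_mix: {single_gene_sanger: 0.45, single_gene_hrm: 0.40,
             single_gene_fish: 0.05, multigene_panel: 0.10}
  mutations_per_patient: {mean: 0.75, min: 0, max: 1}
  categories:
    ema_tt_available: 14
    trial_tt_available: 0
    started_ema_tt: 6
    included_tt_trial: 0
    tt_option_no_start: 5
    trial_without_tt: 1
    started_mab: 5
    started_mab_trial: 2
    started_radio_chemo: 8
    started_operation: 2
    no_treatment_option: 2
    treated_elsewhere: 5
melanoma_after:
  indication: melanoma
  period: after
  n_patients: 36
  tests_per_patient: {mean: 1.67, min: 1, max: 4}
  test_mix: {small_tgp: 0.30, single_gene_sanger: 0.30, single_gene_hrm: 0.10,
             single_gene_fish: 0.10, multigene_panel: 0.20}
  mutations_per_patient: {mean: 1.11, min: 0, max: 3}
  categories:
    ema_tt_available: 21
    trial_tt_available: 0
    started_ema_tt: 3
    included_tt_trial: 2
    tt_option_no_start: 1
    trial_without_tt: 0
    started_mab: 8
    started_mab_trial: 3
    started_radio_chemo: 7
    started_operation: 3
    no_treatment_option: 3
    treated_elsewhere: 6
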