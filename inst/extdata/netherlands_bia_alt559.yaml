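# Alternate national BIA configuration: identical to netherlands_bia.yaml
# except that the NSCLC current-peripheral cell follows the published summary
# table (559) instead of the running text (590 = two single-gene tests at
# 295). See the methods vignette for the discrepancy note.
catalog:
  single_gene_sanger: 295
  single_gene_hrm: 265
  single_gene_fish: 309
  multigene_panel: 500
  small_tgp: 606
  medium_tgp: 1137
  wgs: 1100
populations:
  nsclc:    {old_2012: 4045, current_2015: 4045, future_2020: 4474}
  melanoma: {old_2012: 800,  current_2015: 800,  future_2020: 887}
scenarios:
  - {timeframe: old_2012, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}
  - {timeframe: old_2012, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1103,
     bundle: [{test: multigene_panel, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0},
              {test: single_gene_fish, fraction: 1.0}]}
  - {timeframe: current_2015, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 559,
     bundle: [{test: single_gene_sanger, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0}]}
  - {timeframe: current_2015, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1504,
     bundle: [{test: small_tgp, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0},
              {test: single_gene_fish, fraction: 1.0}]}
  - {timeframe: future_2020, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 606,
     bundle: [{test: small_tgp, fraction: 1.0}]}
  - {timeframe: future_2020, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1100,
     bundle: [{test: wgs, fraction: 1.0}]}
  - {timeframe: old_2012, indication: melanoma, stratum: peripheral,
     patient_share: 0.30, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}
  - {timeframe: old_2012, indication: melanoma, stratum: specialised,
     patient_share: 0.70, printed_cost: 559,
     bundle: [{test: single_gene_hrm, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0}]}
  - {timeframe: current_2015, indication: melanoma, stratum: peripheral,
     patient_share: 0.30, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}
  - {timeframe: current_2015, indication: melanoma, stratum: specialised,
     patient_share: 0.70, printed_cost: 753,
     bundle: [{test: small_tgp, fraction: 1.0},
              {test: single_gene_sanger, fraction: 0.5}]}
  - {timeframe: future_2020, indication: melanoma, stratum: peripheral,
     patient_share: 0.30, printed_cost: 606,
     bundle: [{test: small_tgp, fraction: 1.0}]}
  - {timeframe: future_2020, indication: melanoma, stratum: specialised,
     patient_share: 0.70, printed_cost: 1100,
     bundle: [{test: wgs, fraction: 1.0}]}
sensitivity:
  relative_range: 0.20
  current_additional_tests: [single_gene_sanger, single_gene_sanger, single_gene_fish]
wgs_projection:
  usd_per_genome: 1250
  genomes_per_patient: 4
  reduction_fraction: 0.75
  usd_to_eur: 0.88
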