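# Canonical national BIA configuration: stage-IV NSCLC and melanoma molecular
# diagnostics in The Netherlands across the 2012 / 2015 / 2020 time frames.
#
# Each scenario carries its test bundle (catalog entries with applicability
# fractions) and the published per-stratum bundle cost as printed_cost. The
# catalog sum and the printed column drift by up to one euro (the source
# tables round independently); weighted per-patient costs use printed_cost by
# default so that reconstructed summary cells reproduce the published ones.
#
# The NSCLC current-peripheral cell is 590 (two single-gene tests at 295, per
# the running text); the table variant of 559 ships as the alternate config.
catalog:
  single_gene_sanger: 295    # Sanger sequencing / fragment analysis / sequence analysis
  single_gene_hrm: 265       # high-resolution melting
  single_gene_fish: 309      # fluorescence in situ hybridisation
  multigene_panel: 500       # mass-spectrometry hotspot panel, <10 genes
  small_tgp: 606             # 48-gene amplicon panel, ABC estimate
  medium_tgp: 1137           # 178-gene capture panel, ABC estimate
  wgs: 1100                  # four genomes per patient, projected 2020 price
populations:
  nsclc:    {old_2012: 4045, current_2015: 4045, future_2020: 4474}
  melanoma: {old_2012: 800,  current_2015: 800,  future_2020: 887}
scenarios:
  - {timeframe: old_2012, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}   # EGFR
  - {timeframe: old_2012, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1103,
     bundle: [{test: multigene_panel, fraction: 1.0},       # in-house hotspot panel
              {test: single_gene_sanger, fraction: 1.0},    # fragment analysis HER2/EGFR
              {test: single_gene_fish, fraction: 1.0}]}     # ALK/ROS/RET/MET
  - {timeframe: current_2015, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 590,
     bundle: [{test: single_gene_sanger, fraction: 1.0},    # EGFR
              {test: single_gene_sanger, fraction: 1.0}]}   # ALK
  - {timeframe: current_2015, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1504,
     bundle: [{test: small_tgp, fraction: 1.0},
              {test: single_gene_sanger, fraction: 1.0},    # fragment analysis HER2/EGFR
              {test: single_gene_sanger, fraction: 1.0},    # Sanger EGFR
              {test: single_gene_fish, fraction: 1.0}]}     # ALK/ROS/RET/MET
  - {timeframe: future_2020, indication: nsclc, stratum: peripheral,
     patient_share: 0.70, printed_cost: 606,
     bundle: [{test: small_tgp, fraction: 1.0}]}
  - {timeframe: future_2020, indication: nsclc, stratum: specialised,
     patient_share: 0.30, printed_cost: 1100,
     bundle: [{test: wgs, fraction: 1.0}]}
  - {timeframe: old_2012, indication: melanoma, stratum: peripheral,
     patient_share: 0.30, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}   # BRAF
  - {timeframe: old_2012, indication: melanoma, stratum: specialised,
     patient_share: 0.70, printed_cost: 559,
     bundle: [{test: single_gene_hrm, fraction: 1.0},       # BRAF
              {test: single_gene_sanger, fraction: 1.0}]}   # NRAS or KIT
  - {timeframe: current_2015, indication: melanoma, stratum: peripheral,
     patient_share: 0.30, printed_cost: 295,
     bundle: [{test: single_gene_sanger, fraction: 1.0}]}   # BRAF
  - {timeframe: current_2015, indication: melanoma, stratum: specialised,
     patient_share: 0.70, printed_cost: 753,
     bundle: [{test: small_tgp, fraction: 1.0},
              {test: single_gene_sanger, fraction: 0.5}]}   # KIT, half of patients
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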