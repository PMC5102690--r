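# Activity schedules for the two NGS panels, by sequencing platform.
#
# Monetary fields are euros; time fields are minutes. Platform-dependent
# fields (sequencer depreciation, run consumables) are maps keyed by
# platform. Run-level work (run execution, data sync / run check, and for the
# medium panel the capture batching) carries minutes_per_run, scaled from the
# per-sample timings at the 48-sample batch size; sample-level work carries
# minutes_per_sample.
small_tgp:
  description: "Amplicon-based targeted panel, 48 genes / 212 amplicons"
  max_samples_per_run: {miseq: 48, hiseq: 48}
  steps:
    - {label: "Case acceptance, form printing, database registration",
       role: secretary, minutes_per_sample: 20}
    - {label: "Histological quality check of biopsy, tumour-area selection",
       role: technician, minutes_per_sample: 5.71, equipment_annual: 1309}
    - {label: "Histological quality check, pathologist review",
       role: pathologist, minutes_per_sample: 5}
    - {label: "DNA isolation and quantification",
       role: technician, minutes_per_sample: 14.86,
       material_per_sample: 18, equipment_annual: 2216}
    - {label: "Quality check: quantity and quality control assays",
       role: technician, minutes_per_sample: 13.46,
       material_per_sample: 7, equipment_annual: 3905}
    - {label: "Amplicon library preparation",
       role: technician, minutes_per_sample: 20.36,
       material_per_sample: 130, equipment_annual: 5434}
    - {label: "Run execution including checks",
       role: technician, minutes_per_run: 102.72,
       material_per_run: {miseq: 1198, hiseq: 3528},
       equipment_annual: {miseq: 30229, hiseq: 196020}}
    - {label: "Data synchronisation and run check",
       role: bioinformatician, minutes_per_run: 205.92}
    - {label: "Run check, data analysis, draft conclusion",
       role: technician, minutes_per_sample: 30, equipment_annual: 51236}
    - {label: "Approval of conclusion",
       role: molecular_biologist, minutes_per_sample: 30}
    - {label: "Entry into diagnostic and patient databases",
       role: secretary, minutes_per_sample: 15}
    - {label: "Approval of result and lab form (molecular biologist)",
       role: molecular_biologist, minutes_per_sample: 5}
    - {label: "Approval of result and lab form (pathologist)",
       role: pathologist, minutes_per_sample: 10}
    - {label: "Approval of result and lab form (administration)",
       role: secretary, minutes_per_sample: 10}
    - {label: "Tumour sequencing board discussion",
       role: board_member, minutes_per_sample: 1.5}
    - {label: "General laboratory equipment (additional)",
       role: technician, equipment_annual: 2260}
medium_tgp:
  description: "Capture-based targeted panel, full exons of 178 genes (DNA part)"
  max_samples_per_run: {miseq: 4, hiseq: 48}
  steps:
    - {label: "Case acceptance, form printing, database registration",
       role: secretary, minutes_per_sample: 20}
    - {label: "Histological quality check of biopsy, tumour-area selection",
       role: technician, minutes_per_sample: 5.71, equipment_annual: 1309}
    - {label: "Histological quality check, pathologist review",
       role: pathologist, minutes_per_sample: 5}
    - {label: "DNA isolation",
       role: technician, minutes_per_sample: 12.86,
       material_per_sample: 18, equipment_annual: 2632}
    - {label: "Quality check: quantity and fragment-size control",
       role: technician, minutes_per_sample: 8.57,
       material_per_sample: 118, equipment_annual: 4543}
    - {label: "Preparation (shearing)",
       role: technician, minutes_per_sample: 12.86, equipment_annual: 2991}
    - {label: "Capture library preparation",
       role: technician, minutes_per_sample: 51.43, equipment_annual: 3216}
    - {label: "Capture batching",
       role: technician, minutes_per_run: 925.92,
       material_per_run: 509,
       equipment_annual: {miseq: 30229, hiseq: 196020}}
    - {label: "Run execution including checks",
       role: technician, minutes_per_run: 102.72,
       material_per_run: {miseq: 2427, hiseq: 4926}}
    - {label: "Data synchronisation and run check",
       role: bioinformatician, minutes_per_run: 205.92, equipment_annual: 51236}
    - {label: "Run check, data analysis, draft conclusion",
       role: technician, minutes_per_sample: 6}
    - {label: "Approval of conclusion",
       role: molecular_biologist, minutes_per_sample: 30}
    - {label: "Entry into diagnostic and patient databases",
       role: secretary, minutes_per_sample: 15}
    - {label: "Approval of result and lab form (molecular biologist)",
       role: molecular_biologist, minutes_per_sample: 5}
    - {label: "Approval of result and lab form (pathologist)",
       role: pathologist, minutes_per_sample: 10}
    - {label: "Approval of result and lab form (administration)",
       role: secretary, minutes_per_sample: 10}
    - {label: "Tumour sequencing board discussion",
       role: board_member, minutes_per_sample: 3}
    - {label: "General laboratory equipment (additional)",
       role: technician, equipment_annual: 2260}
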