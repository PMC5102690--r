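# Personnel rates in euros per direct productive minute.
#
# Per-role hourly employer costs are not public; these are calibrated
# constants, solved so that the packaged activity schedules aggregate to the
# published fixed-per-run / variable-per-sample personnel cost decomposition
# of both panels simultaneously. The board rate covers the whole multi-member
# tumour sequencing board, not one person.
secretary: 0.3336
technician: 0.5324
pathologist: 1.00
molecular_biologist: 0.60
bioinformatician: 1.4195
board_member: 16.7046
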