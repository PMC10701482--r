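# Default analysis configuration for qcstability.
# TCL multipliers follow the usual stability criterion:
# TCL = sqrt((1.65*CVa)^2 + (0.5*CVb)^2), CVa-only when no CVb exists.
tcl:
  cva_multiplier: 1.65
  cvb_multiplier: 0.5
tier_fractions:
  optimal: 0.25
  desirable: 0.50
  minimum: 0.75
rule:
  min_days: 2
  consecutive: false
study_ends:
  MQ: 15
  UC: 15
  LI: 20
  LL: 20
matrix_map:
  MQ: serum
  LI: serum
  LL: serum
  UC: urine
rounding_digits: 2
csv_dialect: standard
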