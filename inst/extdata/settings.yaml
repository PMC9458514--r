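# Model run settings and structural conventions.
horizon_cycles: 144          # 12 years of monthly cycles
cycle_length_months: 1
discount_rate_annual: 0.03
wtp_primary: 100000
wtp_thresholds: [50000, 100000, 150000]
psa_iterations: 10000
rng_seed: 1
# Destination split for patients who drop out of neoadjuvant therapy
# ("second-line treatment, palliative care, or died"; proportions are an
# explicit modelling choice, no published split exists).
dropout_split:
  second_line: 0.5
  palliative: 0.3
  death: 0.2
# Per-protocol capecitabine/radiation + chemoradiation-hospitalization add-on
# during the final two neoadjuvant cycles.
chemoradiation_addon: true
# Number of post-resection cycles valued at the surgery-recovery utility.
surgery_recovery_cycles: 1
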