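# Center-of-excellence scenario: SYNTHETIC placeholder override values.
# The published scenario adjusted dropout, recurrence and R0 rates to
# center-of-excellence literature, but the exact values were not printed in
# the main text; the numbers below follow the stated qualitative direction
# (lower dropout, lower recurrence, higher R0) and are illustrative only.
# Scenario outputs are therefore not comparable to the published scenario
# results.
name: center_of_excellence_synthetic
strategies:
  FOLFIRINOX:
    dropout_rate: 0.25
    recurrence_rate: 0.55
    r0_rate: 0.88
  G-nP:
    dropout_rate: 0.22
    recurrence_rate: 0.48
    r0_rate: 0.85
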