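# Natural-history comparator: untreated BR/LA PDAC, no neoadjuvant therapy,
# no surgery. Carries no chemotherapy fields by construction.
name: "natural history"
n_cycles: 0
cycle_days: "none"
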