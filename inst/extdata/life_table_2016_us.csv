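# Abridged all-cause mortality, male/female average of the 2016 U.S. period
# life table (annual probability of death q_x), ages spanning the 12-year
# model horizon from entry at age 60. Values are approximate transcriptions
# rounded to 4 decimals; converted to monthly probabilities in code via
# 1 - (1 - q)^(1/12).
age,annual_mortality
60,0.0091
61,0.0098
62,0.0105
63,0.0113
64,0.0122
65,0.0132
66,0.0143
67,0.0155
68,0.0168
69,0.0183
70,0.0200
71,0.0219
72,0.0240
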