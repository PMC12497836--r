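# AT-403 0.1 mg/kg s.c. at ZT2: ~6 h NREM promotion, REM suppression,
# reduced wake drive (shorter NREM latency)
onset_zt: 2
duration_h: 6
wake_propensity_mult: 0.526
nrem_bout_mult: 1.5
rem_bout_mult: 0.556
latency_delay_min: 4.21
label: at403
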