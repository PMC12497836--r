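# meloxicam (NSAID): no sleep-architecture effect
onset_zt: 2
duration_h: 4
wake_propensity_mult: 1
nrem_bout_mult: 1
rem_bout_mult: 1
latency_delay_min: 8
label: meloxicam
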