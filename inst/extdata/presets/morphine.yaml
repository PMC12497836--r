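# morphine 3 mg/kg i.p. at ZT2: ~4 h NREM/REM suppression and a marked
# sleep-latency delay
onset_zt: 2
duration_h: 4
wake_propensity_mult: 1.6
nrem_bout_mult: 0.735
rem_bout_mult: 0.571
latency_delay_min: 48.8
label: morphine
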