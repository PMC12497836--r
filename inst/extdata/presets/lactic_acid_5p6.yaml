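# 5.6% lactic acid i.p. at ZT2: transient (~1.5 h) wake promotion with
# NREM and REM suppression
onset_zt: 2
duration_h: 1.5
wake_propensity_mult: 3.016
nrem_bout_mult: 0.498
rem_bout_mult: 0.351
latency_delay_min: 24.13
label: lactic_acid
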