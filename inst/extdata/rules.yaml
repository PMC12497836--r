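epoch_length_s: 10
nrem_latency_min_bout_s: 30
rem_latency_min_bout_s: 20
brief_arousal_min_s: 20
brief_arousal_max_s: 30
arousal_tolerant_bouts: false
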