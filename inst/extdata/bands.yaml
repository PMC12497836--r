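delta: [0.5, 4]
theta: [4, 8]
alpha: [8, 12]
sigma: [12, 16]
beta: [16, 24]
low_gamma: [30, 50]
high_gamma: [50, 100]
total_gamma: [30, 100]
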