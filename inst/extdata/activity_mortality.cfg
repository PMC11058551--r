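prevalence: 0.6
baseline_prob: 0.5
log_odds_ratio: -1.0986122886681098
beta0: -4.9618451299268228
beta1: -0.22314355131420976
beta2: 1.3862943611198906
gamma: 1.1
tau: 10
n: 5000
alpha: 0.05
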