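model: seriality
organ: heart
endpoint: cardiac_mortality
d50: 70.3
gamma: 0.96
s: 1
horizon_years: 15

model: schneider
organ: lung
endpoint: lung_cancer
rf: 0.84
alpha: 0.061
mu: 2.7
horizon_years: 30

model: schneider
organ: breast
endpoint: breast_cancer
rf: 0.62
alpha: 0.067
mu: 4.8
horizon_years: 30
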