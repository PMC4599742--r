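# 1-D birth-death chain: constant birth, linear death
model: custom
params:
  lambda: 5
  mu: 1
channels:
  - shift: [1]
    propensity: "lambda"
  - shift: [-1]
    propensity: "mu * x1"
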