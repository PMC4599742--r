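# bistable toggle switch with the classical rate constants
model: toggle2d
params:
  c1: 3000
  c2: 11000
  c3: 0.001
  c4: 3000
  c5: 11000
  c6: 0.001
  beta: 2
  gamma: 2
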