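design:
  N: 92
  r: [0.25, 0.75, 0.0]
  rule: opt
arms:
  means: [4.94, 5.66, 5.66]
  sds: [1.0, 1.0, 1.0]
analysis:
  mode: cc
  test: t
  alpha: 0.025
simulation:
  nsim: 10000
  seed: 42
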