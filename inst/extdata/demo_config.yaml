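regions:
  - SEA-like
  - ESSA-like
horizon: 100
discount_rate: 0.03
coverages: [0.5, 0.8, 0.95]
seed: 1
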