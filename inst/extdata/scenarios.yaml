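# Six reference scenarios: three rate schedules crossed with two
# educational-level distributions (ELD1 left-skewed, ELD2 upward-shifted).
scenarios:
  A: {shares: [0.40, 0.25, 0.25, 0.10], rates: [750, 550, 450, 300]}
  B: {shares: [0.20, 0.25, 0.25, 0.30], rates: [750, 550, 450, 300]}
  C: {shares: [0.40, 0.25, 0.25, 0.10], rates: [630, 500, 400, 290]}
  D: {shares: [0.20, 0.25, 0.25, 0.30], rates: [630, 500, 400, 290]}
  E: {shares: [0.40, 0.25, 0.25, 0.10], rates: [750, 570, 420, 260]}
  F: {shares: [0.20, 0.25, 0.25, 0.30], rates: [750, 570, 420, 260]}
baseline: A
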