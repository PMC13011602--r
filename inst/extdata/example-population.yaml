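# Single-cell population near the threshold: structural components
# heterogeneous (beta-distributed), permissiveness fixed at 1 (late G1/S).
seed: 42
gate:
  threshold: 0.25
  sharpness: 8
components:
  A: {dist: {family: beta, shape1: 2, shape2: 2}}
  D: {dist: {family: beta, shape1: 2, shape2: 2}}
  C: {dist: {family: beta, shape1: 2, shape2: 2}}
  phi: {value: 1}
population:
  n_cells: 2000
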