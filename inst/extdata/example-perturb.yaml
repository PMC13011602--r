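# Factorial perturbation experiment: 3 licensing x 2 drive x 2 chromatin
# scales, multiplicative generative truth, per-cell component noise 0.05.
seed: 11
gate:
  threshold: 0.5
perturb:
  levels:
    A: [1.0, 0.7, 0.4]
    D: [1.0, 0.5]
    C: [1.0, 0.5]
  replicates: 1
  n_cells: 1000
  noise_sd: 0.05
  truth: multiplicative
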