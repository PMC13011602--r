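# repgate configuration schema

Configuration files are YAML (primary) or JSON (`.json` extension).
Unknown keys anywhere in the file are rejected. All keys are optional;
defaults in brackets.

```yaml
seed: <int>                # root seed for all randomness [1]
out_dir: <path>            # default output directory ["."]
log_level: debug|info|warn|error   # [info]

gate:
  threshold: <0..1]        # initiation threshold [0.5]
  sharpness: <positive>    # Hill exponent of the graded response [8]

components:                # per-component block; keys A, D, C, phi
  A:
    value: <0..1>          # fixed value (wins over dist)
    dist:                  # sampling distribution for population runs
      family: beta|fixed   # [beta]
      shape1: <pos>        # beta shape [2]
      shape2: <pos>        # beta shape [2]
      value: <0..1>        # for family fixed [1]
    normalization:         # raw-correlate scaling
      lo: <raw units>      # mapped to 0
      hi: <raw units>      # mapped to 1 (must exceed lo)
      clamp: true|false    # clip out-of-range raw values [true]

population:
  n_cells: <int >= 1>      # [1000]

cycle:
  schedule:                # ordered segments; default G1(ramp)/S/G2/M
    - {phase: G0|G1|S|G2|M, duration: <h>, phi_start: <0..1>, phi_end: <0..1>}
  g1_ramp: true|false      # only for the default schedule [true]
  k_act: <pos>             # activation gain, 1/h [1]
  gamma: <pos>             # decay gain, 1/h [1]
  dt: <pos>                # Euler step, h; must divide durations [0.01]
  noise_sd: <>= 0>         # per-step component jitter sd [0]
  n_origins: <int>         # generated origins when no file given [50]
  origins_file: <path>     # CSV/TSV with columns id, A, D, C, threshold
  stochastic_firing: true|false   # Bernoulli firing at the graded rate [false]
  events:
    - {t_start: <h>, t_end: <h>, phi_scale: <0..1>, D_scale: <0..1>}

perturb:
  levels:                  # factorial scales; each list must include 1.0
    A: [1.0, 0.7, 0.4]
    D: [1.0, 0.5]
    C: [1.0, 0.5]
  replicates: <int>        # [1]
  n_cells: <int>           # per condition and replicate [1000]
  noise_sd: <>= 0>         # per-cell component noise [0.05]
  truth: multiplicative|additive  # generative model [multiplicative]

fixtures:
  n_samples: <int>         # [100]
  regime: stem|quiescent|stressed  # [stem]
```

Tables are RFC-4180 CSV or TSV; fit summaries and provenance are JSON.
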