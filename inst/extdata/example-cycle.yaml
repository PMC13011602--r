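# One cell cycle with a mid-S checkpoint window (DNA-damage arrest):
# permissiveness and drive are scaled down inside the window, producing a
# reversible below-threshold arrest interval.
seed: 7
gate:
  threshold: 0.5
cycle:
  n_origins: 50
  k_act: 1.0
  gamma: 1.0
  dt: 0.01
  events:
    - {t_start: 13, t_end: 15, phi_scale: 0.1, D_scale: 0.8}
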