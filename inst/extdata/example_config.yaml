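geometry:
  lenslet_count: 8
  pupil_diameter_mm: 2.4
dataset:
  n_train: 500
  n_val: 100
  n_test: 100
  input_side: 64
  seed: 1
train:
  profile: desk
  epochs: 10
  lr0: 0.001
protocol:
  threshold: 0.0894
  tol: 0.001
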