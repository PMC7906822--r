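# Desk-scale end-to-end profile: two synthetic subjects, one run of 48
# balanced trials per session, strong ERD (amplitude attenuation 0.5), and a
# reduced-width network so the full pipeline runs on a single CPU.
seed: 7
subjects: 2
simulation:
  n_runs: 1
  trials_per_run: 48
  n_channels: 22
  attenuation: 0.5
windowing:
  train: [2, 6, 1, 1]
  test: [4, 5, 1, 1]
augmentation:
  hidden_dim: 64
  lr: 0.05
  n_iters: 60
  factor: 1
network:
  conv_filters: [6, 6, 12, 12]
  fc_width: 32
  attention_dim: 16
training:
  learning_rate: 0.001
  minibatch: 200
  epochs: 30
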