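# Quickstart: a small tree network (K = 2 kernels per channel, M = 4
# branches) on the bundled synthetic 10-class task. Trains in a few minutes
# on one CPU and comfortably beats chance.
seed: 1
architecture:
  variant: tree3
  channels: 1
  filters: 2
  branches: 4
  height: 12
  width: 12
  filter_size: 5
  pool_size: 2
  slab_rows: 2
  classes: 10
  activation: relu
data:
  source: synthetic
  train_per_class: 40
  test_per_class: 20
  amplitude: 1.0
  noise_sd: 0.3
training:
  lr: 0.05
  momentum: 0.9
  weight_decay: 5.0e-5
  batch_size: 20
  epochs: 15
  engine: reference
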