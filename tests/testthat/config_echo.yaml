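selection:
  a1: 0.2
  lambda: 0.5
  tol: 1.0e-07
  max_iter: 5000
  standardize: yes
encoder:
  widths:
  - 1000
  - 100
  - 100
  activation: tanh
  pretrain: yes
  pretrain_epochs: 50
  pretrain_lr: 0.001
fusion:
  mode: fuse
  position: 3
  K: 100
  pairing: consecutive
loss:
  gamma: 1.0
  margin: 1.0
  lambda1: 0.5
  lambda2: 0.1
train:
  epochs: 300
  batch_size: 96
  learning_rate: 0.0001
cv:
  n_folds: 5
  seed: 0
io:
  out_dir: '.'
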