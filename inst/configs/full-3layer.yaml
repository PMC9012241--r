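# Full-scale 3-layer variant; only depth and the peak learning rate differ
# from full-6layer.yaml.
model:
  l: 512
  f: 512
  h: 8
  n_layers: 3
  d_emb: 16
  scales: [5, 10, 20]
  channels_per_size: 16
  dropout: 0.1
pretrain:
  warmup_steps: 50000
  peak_lr: 0.0001
  batch_size: 32
  max_epochs: 300
  mask_fraction: 0.15
  action_probs: {mask: 0.8, random: 0.1, keep: 0.1}
finetune:
  initial_lr: 0.00001
  decay_factor: 0.95
  decay_every: 100
  weight_decay: 0.0001
  batch_size: 128
  max_epochs: 100
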