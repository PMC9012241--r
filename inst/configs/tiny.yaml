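# Desk-scale configuration: small enough to pre-train and fine-tune on one
# CPU in minutes. Learning rates are scaled up relative to the full-scale
# configuration in proportion to the much smaller model and step count.
model:
  l: 128
  f: 64
  h: 2
  n_layers: 2
  scales: [5, 10, 20]
  channels_per_size: 4
  dropout: 0.1
pretrain:
  warmup_steps: 200
  peak_lr: 0.001
  batch_size: 32
  max_epochs: 2
  mask_fraction: 0.15
  action_probs: {mask: 0.8, random: 0.1, keep: 0.1}
finetune:
  initial_lr: 0.001
  decay_factor: 0.95
  decay_every: 100
  weight_decay: 0.0001
  batch_size: 32
  max_epochs: 3
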