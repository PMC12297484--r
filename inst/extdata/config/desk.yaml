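# Desk-scale experiment preset: ~120 synthetic cardiac-like segments,
# compact encoder, batch 32, 20 epochs. The "large" train preset holds the
# GPU-scale settings (batch 1024, 1000 epochs, 128 prototypes).
synth:
  n_classes: 4
  n_subjects: 12
  segments_per_subject: 10
  channels: 1
  fs: 100
  window_s: 10
  class_sep: 1.0
features:
  modality: cardiac
split:
  ratios: [0.6, 0.2, 0.2]
train:
  preset: desk
probe:
  k: 10
finetune:
  epochs: 15
  lr: 0.0005
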