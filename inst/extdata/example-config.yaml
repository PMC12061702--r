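# Example run configuration for the tonguenet CLI (desk-scale profile).
max_steps: 200
epochs: 12
seed: 1
hidden_channels: 16
n_levels: 3
conv_groups: 4
embed_dim: 32
text_hidden: 48
kan_hidden: 32
dropout: 0
generator:
  n_samples: 400
  image_size: 32
  effect_size: 2
  cross_modal_agreement: 1
  seed: 11
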