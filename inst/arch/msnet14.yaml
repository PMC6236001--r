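# 14-layer MS/HC slice classifier: 11 conv + 3 fully-connected layers.
# Pooling, batch norm, dropout and softmax are uncounted sublayers.
input:
  side: 256
  channels: 1
pooling: stochastic
layers:
  - {type: conv, name: conv_1, kernel: 3, in_channels: 1, out_channels: 8, stride: 2}
  - {type: pool, name: pool_1, kernel: 3, stride: 2}
  - {type: conv, name: conv_2, kernel: 3, in_channels: 8, out_channels: 8, stride: 2}
  - {type: pool, name: pool_2, kernel: 3, stride: 2}
  - {type: conv, name: conv_3, kernel: 3, in_channels: 8, out_channels: 16, stride: 1}
  - {type: conv, name: conv_4, kernel: 3, in_channels: 16, out_channels: 16, stride: 1}
  - {type: conv, name: conv_5, kernel: 3, in_channels: 16, out_channels: 16, stride: 1}
  - {type: pool, name: pool_3, kernel: 3, stride: 2}
  - {type: conv, name: conv_6, kernel: 3, in_channels: 16, out_channels: 32, stride: 1}
  - {type: conv, name: conv_7, kernel: 3, in_channels: 32, out_channels: 32, stride: 1}
  - {type: conv, name: conv_8, kernel: 3, in_channels: 32, out_channels: 32, stride: 1}
  - {type: conv, name: conv_9, kernel: 3, in_channels: 32, out_channels: 64, stride: 1}
  - {type: conv, name: conv_10, kernel: 3, in_channels: 64, out_channels: 64, stride: 1}
  - {type: conv, name: conv_11, kernel: 3, in_channels: 64, out_channels: 64, stride: 1}
  - {type: pool, name: pool_4, kernel: 3, stride: 2}
  - {type: flatten, name: flatten}
  - {type: fc, name: fc_1, out_dim: 20}
  - {type: dropout, name: do_1, p: 0.5}
  - {type: fc, name: fc_2, out_dim: 10}
  - {type: dropout, name: do_2, p: 0.5}
  - {type: fc, name: fc_3, out_dim: 2}
  - {type: softmax, name: softmax}
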