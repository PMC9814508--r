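# Built-in architecture zoo: structure strings are data, not code.
# input: "sequence" feeds (T, F) into recurrent layers; "image" feeds
# (T, F, 1) into convolutional layers.
lstm:
  input: sequence
  structure: "LSTM (64)-Drop (0.5)-FC(64)-FC (3)"
gru:
  input: sequence
  structure: "GRU (64)-Drop (0.5)-FC(64)-FC (3)"
cnn:
  input: image
  structure: "Conv [16, (3,3)]-MaxPooling (3,3)-Conv [32, (3,3)]-MaxPooling (3,3)-Conv [64, (3,3)]-MaxPooling (3,3)-Conv [128, (3,3)]-MaxPooling (3,3)-Drop (0.5)-GlobalAveragePooling ()-Dense (3)"
resnet:
  input: image
  structure: "Conv [8, (3,3)]-BN-Conv [8, (3,3)]-residual {Conv [16, (1,1)]-BN}-SeparableConv [16, (3,3)]-BN-MaxPooling (3,3)-add-residual {Conv [32, (1,1)]-BN}-SeparableConv [32, (3,3)]-BN-SeparableConv [32, (3,3)]-BN-MaxPooling (3,3)-add-residual {Conv [64, (1,1)]-BN}-SeparableConv [64, (3,3)]-BN-SeparableConv [64, (3,3)]-BN-MaxPooling (3,3)-add-residual {Conv [128, (1,1)]-BN}-SeparableConv [128, (3,3)]-BN-MaxPooling (3,3)-add-Conv [3, (3,3)]-GlobalAveragePooling ()"
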