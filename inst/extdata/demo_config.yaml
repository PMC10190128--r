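# Small demonstration run: two cell types, 120 cells each, light LSTM.
seed: 1
nCellsPerType: 120
populations: ["A549", "CAL27"]
channel:
  noiseSdMv: 1.5
  spillover: identity
train:
  lstmHidden: 16
  batchSize: 40
  learningRate: 0.005
  maxEpochs: 5
  seqLength: 128
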