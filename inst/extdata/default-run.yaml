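# Example run configuration for mepmuscle::runPipeline() /
# inst/scripts/mep-pipeline.R.  Omitted keys keep package defaults
# (36 patients, full per-muscle trace counts, full tuning grids).
nPatients: 36
tracesPerPatient:
  EXT: 20
  APB: 25
  TA: 24
  AH: 20
nTrain: 28
nTest: 8
reducedGrids: yes
cvFolds: 3
seed: 11
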