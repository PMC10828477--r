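# Small self-contained demo run: simulate a paired-tissue cohort and carry it
# through QC, EWAS, partition, clock training and the rate comparison.
seed: 42
simulation:
  nSubjects: 120
  nDatasets: 3
  noiseSd: 0.01
  cpgCounts:
    shared_age: 40
    tissueA_only: 30
    tissueB_only: 60
    "null": 300
    sex_linked: 30
clocks:
  nFolds: 5
rates:
  transform: identity
  selfCV: none
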