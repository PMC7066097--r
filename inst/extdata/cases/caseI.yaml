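caseId: I
modality: EMEG
sparsity: 8.0
nDecompositions: 100
hyperprior: IG
deepAmplitude: 10.0
superficialAmplitude: 7.0
noisePct: 3.0
nRealizations: 50
nLevels: 3
nIter: 10
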