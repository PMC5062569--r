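# Small end-to-end demo configuration for runPipeline().
seed: 7
stages: [simulate, classify, correlate, timeseries, genescan, cost]
sim:
  nPopulations: 6
  nPerPopulation: 25
  ancestryMeans: [0.2, 0.33, 0.46, 0.59, 0.72, 0.85]
  nGenes: 60
  nVariants: 3000
  nReleases: 8
  depositRelease: 6
  depositNBiased: 15
  depositNNeutral: 60
  nReferenceAfricans: 5
filter:
  pavMafCutoff: 0.05
  navMafCutoff: 0.02
  minDeleteriousCalls: 2
cost:
  costPerConfirmation: 500
  afrThreshold: 0.5
  eurThreshold: 0.35
alpha: 0.05
coverage: 0.9
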