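# Demo calibration scenario: a small bird-like declining history with a
# simulated +3%/yr future, sized to run in well under a minute.
history:
  profile:
    nSpecies: 10
    nYears: 15
    meanGrowth: 0.98
    sdInterspecific: 0.02
    sdInterannual: 0.02
    sdMeasurement: 0.01
    label: demo-bird-like
sim:
  meanGrowth: 1.03
  sdInterspecific: 0.02
  sdInterannual: 0.02
  sdMeasurement: 0.01
  nYears: 5
knots: [5]
nRuns: 2
masterSeed: 7
presmoothFactor: 0.3
mcmc:
  nChains: 2
  nDraws: 400
  nWarmup: 800
  nAdapt: 500
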