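# Desk-scale version of the p2 = 0.35 simulation scenario: the population
# and record-source sizes are reduced (N 1e6, n2 2e4) and the replicate
# count to 100; survey size and linked count stay at 500.
scenario: p235_scaled
params:
  N: 1.0e+6
  phi: 1.5
  gamma: [.na.real, 0.3, 0.3]
  beta: [.na.real, 0.3, 0.3]
  target_p1: 0.30
  target_p2: 0.35
  a: [1, 1, 1, 0.187]
  b: [1, 1, 1, 0.187]
  n1: 500
  n2: 2.0e+4
  overlap: 1.0
  seed: 1
replicates: 100
estimators: [survey, ehr, mosteller]
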