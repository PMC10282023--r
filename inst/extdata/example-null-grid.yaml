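# Simulation grid configuration for `circart simulate`.
# study: null (type-I error), dispersion, or shift
study: null
# family: von_mises, axial_von_mises, or wrapped_skew_normal
family: von_mises
# swept parameter values: shared kappa/rho (null), sample-2 kappa/rho
# (dispersion), or location shift in degrees (shift)
sweep: [0, 2, 8]
# sample-size pairs [m, n]
sizes:
  - [10, 10]
  - [10, 50]
# tests to run (any subset of ART, WU2, pWU2, WW, pWW, Rsf)
tests: [ART, WU2, pWU2, WW, pWW, Rsf]
# Monte-Carlo scale; --paper-scale overrides to 10000 / 10000
n_replicates: 1000
n_permutations: 999
# significance level: reject when p <= level
level: 0.05
seed: 1
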