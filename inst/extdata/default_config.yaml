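# Default pipeline meta-parameters (study defaults).
pattern: TMD_F
seed: 1
threshold_quantile: 0.80
tmd_ref: 51        # TMD semantic decision boundary (T-score)
f_ref: 52          # F semantic decision boundary (T-score)
T_m: 0.08          # GHSOM breadth threshold
normalization: zscore
som:
  alpha0: 0.1      # learning coefficient
  psi0: 40         # initial neighborhood radius
  O: 200           # maximum learning epochs
  J: 50            # lattice width
  K: 50            # lattice height
rsom:
  n_units: 15
  betas: [0.5, 0.2, 0.3]
  gamma0: 0.1
  O: 200
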