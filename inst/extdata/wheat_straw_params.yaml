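# Optimised kinetic constants for SO2-catalysed steam pre-treated wheat straw.
# The first four were estimated from 10 % w/w WIS batch hydrolysis time
# courses (95 % confidence intervals given); the rest are fixed fermentation
# constants for S. cerevisiae KE6-12.A.
params:
  k_ad: 0.27        # g solid FPU^-1 h^-1
  k: 0.016          # g cellulose FPU^-1 h^-1
  K_G: 6.13         # g kg^-1
  gamma: 0.028      # dimensionless
  K_iEtOH: 16.6     # g kg^-1
  q_G: 1.6          # g g^-1 h^-1
  K: 0.01           # g kg^-1
  Y_EtOH: 0.42      # g g^-1
  alpha: 0.026      # h^-1
  beta: 0.0037      # kg g^-1
confidence_intervals:
  k_ad: [0.03, 0.5]
  k: [0.009, 0.03]
  K_G: [2.7, 13.8]
  gamma: [0.01, 0.08]
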