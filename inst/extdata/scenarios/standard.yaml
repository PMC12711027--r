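# Standard competition scenario: wildtype at its single-plasmid
# equilibrium, invaded by co-infected cells carrying a mutant with a
# two-fold horizontal transmission advantage.
params:
  rho: 1
  c: 0.1
  gamma: 0.1
  K: 1
  beta_W: 1
  beta_M: 2
  s_W: 0.1
  s_M: 0.1
  k: 0.99
  epsilon: 0
initial: standard
criterion:
  mode: absolute_density
  threshold: 0.01
t_max: 100000
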