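# Example run configuration: dimensionless parameters of a fully
# competitive scheme with a strong steady-state timescale split.
dimensionless:
  eta_S: 0.2
  eps_S: 4.1
  kappa_S: 3.1
  eta_I: 0.1
  eps_I: 1.2
  kappa_I: 0.1
  rho: 10
integrator:
  method: reference
seed: 1
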