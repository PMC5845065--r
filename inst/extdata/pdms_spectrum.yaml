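# Modal decay spectrum of a PDMS graft in a carotid-sized conduit
output: spectrum
n_max: 50
seed: 1
material:
  model: zener
  E0_MPa: 2.114
  E1_MPa: 0.9365
  tau_s: 0.2611
geometry:
  r_mm: 4
  e_mm: 0.5
  L: 1
  rho: 1000
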