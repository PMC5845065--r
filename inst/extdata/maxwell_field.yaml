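# Underdamped Maxwell validation run: tau = 2 s, c = 5 m/s, L = 10 m
output: field
seed: 1
material:
  model: maxwell
  E1_Pa: 5.0e6    # gives c = 5 m/s in this tube
  tau_s: 2
geometry:
  r_mm: 10
  e_mm: 1
  L: 10
  rho: 1000
pulse:
  p_max: 1
  T: 0.2
grid:
  N: 512
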