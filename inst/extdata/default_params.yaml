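# Canonical vsemap model parameters.
# Units: cm^-1, Angstrom, degrees, MV/cm, Debye.
vse:
  nu0: 2232.0          # zero-field frequency, cm^-1 (scaled gas-phase anchor)
  dmu: 0.2748          # Stark tuning rate, cm^-1/(MV/cm)
  dalpha: 0.0          # difference polarizability, cm^-1/(MV/cm)^2
  tdm0: 0.040          # zero-field transition dipole, D
  tdm_polarizability: -2.5e-4   # D/(MV/cm)
  tdm_quad: 0.0        # D/(MV/cm)^2
blueshift:
  d0: 3.36             # side-on zero-crossing distance, A
  dnu_d0: 16.6         # head-on blueshift at d0, cm^-1
  b: 2.85              # side-on exponential decay, A^-1
  m: 0.91              # cosine period modulation
  n1: -4               # head-on power exponent (fixed integer)
  n2: -8               # side-on power exponent (fixed integer)
  a: 1.30              # exponential head-on variant decay, A^-1
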