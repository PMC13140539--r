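# Flux and pool bounds for the toy model; config values win over SBML.
compartments: [c]
flux_bounds:
  R1: [0.1, 10]
  R2: [0.1, 10]
  R3: [0.1, 10]
pool_bounds:
  "B[c]": [0.5, 5]
  "D[c]": [0.5, 5]
n_atoms:
  "A[c]": 2
  "B[c]": 2
  "C[c]": 1
  "D[c]": 1
tracer:
  metabolite: "A[c]"
  fractions: 1
  switch_time: 0
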