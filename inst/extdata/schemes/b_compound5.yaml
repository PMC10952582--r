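# Compound-5 scheme: analogue (P) binds the GABA-bound closed state RA to
# form RAP, which can proceed to a deep blocked closed state RAPd.
id: b_compound5
resting: R
states: [R, RA, "RA*", RD, RAP, RAPd]
conducting: ["RA*"]
transitions:
  - {from: R,     to: RA,    rate: k1,        ligand: gaba}
  - {from: RA,    to: R,     rate: k-1,       ligand: none}
  - {from: RA,    to: "RA*", rate: beta,      ligand: none}
  - {from: "RA*", to: RA,    rate: alpha,     ligand: none}
  - {from: "RA*", to: RD,    rate: delta1,    ligand: none}
  - {from: RD,    to: "RA*", rate: "delta-1", ligand: none}
  - {from: RA,    to: RAP,   rate: k2,        ligand: analogue}
  - {from: RAP,   to: RA,    rate: k-2,       ligand: none}
  - {from: RAP,   to: RAPd,  rate: k3,        ligand: none}
  - {from: RAPd,  to: RAP,   rate: k-3,       ligand: none}
rates:
  k1:      {value: 9.79e+08, units: M-1s-1}
  k-1:     {value: 1.25e+04, units: s-1}
  beta:    {value: 6.10e+03, units: s-1}
  alpha:   {value: 2.28e+03, units: s-1}
  delta1:  {value: 2.48e-01, units: s-1}
  delta-1: {value: 3.90e-02, units: s-1}
  k2:      {value: 6.29e+04, units: M-1s-1}
  k-2:     {value: 2.33e-01, units: s-1}
  k3:      {value: 9.21e+05, units: s-1}
  k-3:     {value: 1.40e-01, units: s-1}
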