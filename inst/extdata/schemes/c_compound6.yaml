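# Compound-6 scheme: analogue (P) binds the GABA-bound closed state RA
# (forming RAP) and the desensitised state RD (forming RDP). The published
# legend does not name which association pair sits on which edge; this file
# carries the "standard" assignment (k2/k-2 on RA<->RAP, k4/k-4 on RD<->RDP,
# mirroring the compound-5 scheme); the loader can swap it.
id: c_compound6
resting: R
states: [R, RA, "RA*", RD, RAP, RDP]
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
  - {from: RD,    to: RDP,   rate: k4,        ligand: analogue}
  - {from: RDP,   to: RD,    rate: k-4,       ligand: none}
rates:
  k1:      {value: 3.27e+08, units: M-1s-1}
  k-1:     {value: 2.00e+04, units: s-1}
  beta:    {value: 1.44e+04, units: s-1}
  alpha:   {value: 1.45e+04, units: s-1}
  delta1:  {value: 8.72e-01, units: s-1}
  delta-1: {value: 9.22e-02, units: s-1}
  k2:      {value: 1.29e+05, units: M-1s-1}
  k-2:     {value: 9.00e-02, units: s-1}
  k4:      {value: 2.34e+05, units: M-1s-1}
  k-4:     {value: 1.84e+02, units: s-1}
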