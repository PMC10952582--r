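# Expanded compound-6 scheme with an explicit preactivated (flip) state RfA
# between RA and the open state; the analogue binds RfA (forming RfAP)
# instead of RA, plus the desensitised state RD (forming RDP). "standard"
# assignment: k2/k-2 on RfA<->RfAP, k4/k-4 on RD<->RDP.
id: d_preactivated
resting: R
states: [R, RA, RfA, "RA*", RD, RfAP, RDP]
conducting: ["RA*"]
transitions:
  - {from: R,     to: RA,    rate: k1,        ligand: gaba}
  - {from: RA,    to: R,     rate: k-1,       ligand: none}
  - {from: RA,    to: RfA,   rate: f1,        ligand: none}
  - {from: RfA,   to: RA,    rate: "f-1",     ligand: none}
  - {from: RfA,   to: "RA*", rate: beta,      ligand: none}
  - {from: "RA*", to: RfA,   rate: alpha,     ligand: none}
  - {from: "RA*", to: RD,    rate: delta1,    ligand: none}
  - {from: RD,    to: "RA*", rate: "delta-1", ligand: none}
  - {from: RfA,   to: RfAP,  rate: k2,        ligand: analogue}
  - {from: RfAP,  to: RfA,   rate: k-2,       ligand: none}
  - {from: RD,    to: RDP,   rate: k4,        ligand: analogue}
  - {from: RDP,   to: RD,    rate: k-4,       ligand: none}
rates:
  k1:      {value: 3.27e+08, units: M-1s-1}
  k-1:     {value: 2.00e+04, units: s-1}
  f1:      {value: 1.03e+04, units: s-1}
  f-1:     {value: 1.05e+04, units: s-1}
  beta:    {value: 1.18e+04, units: s-1}
  alpha:   {value: 1.43e+04, units: s-1}
  delta1:  {value: 1.18e+00, units: s-1}
  delta-1: {value: 8.07e-02, units: s-1}
  k2:      {value: 1.73e+05, units: M-1s-1}
  k-2:     {value: 1.05e-01, units: s-1}
  k4:      {value: 1.84e+05, units: M-1s-1}
  k-4:     {value: 3.07e+02, units: s-1}
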