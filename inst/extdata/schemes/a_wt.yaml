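# Simplified GABA-A receptor gating scheme: resting (R), GABA-bound closed
# composite (RA), open (RA*), desensitised (RD). No analogue-bound states.
# GABA-arm rate values are those of the compound-6 scheme fit (model c).
id: a_wt
resting: R
states: [R, RA, "RA*", RD]
conducting: ["RA*"]
transitions:
  - {from: R,     to: RA,    rate: k1,        ligand: gaba}
  - {from: RA,    to: R,     rate: k-1,       ligand: none}
  - {from: RA,    to: "RA*", rate: beta,      ligand: none}
  - {from: "RA*", to: RA,    rate: alpha,     ligand: none}
  - {from: "RA*", to: RD,    rate: delta1,    ligand: none}
  - {from: RD,    to: "RA*", rate: "delta-1", ligand: none}
rates:
  k1:      {value: 3.27e+08, units: M-1s-1}
  k-1:     {value: 2.00e+04, units: s-1}
  beta:    {value: 1.44e+04, units: s-1}
  alpha:   {value: 1.45e+04, units: s-1}
  delta1:  {value: 8.72e-01, units: s-1}
  delta-1: {value: 9.22e-02, units: s-1}
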