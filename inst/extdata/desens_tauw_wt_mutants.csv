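# Extent of macroscopic desensitisation (percent, after 20 s of 1 mM GABA)
# and weighted decay time constant (s) for wild-type alpha1beta3gamma2L and
# two desensitisation-gate mutants.
receptor,desens_percent,tauw_s
wt,68,3.7
a1_V296L,39,7.4
g2_V262F,89,2.3
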