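# Published inhibition potencies of the C-21 pregnenolone sulfate analogues
# (compounds 2-8) on alpha1beta3gamma2L GABA-A receptor currents evoked by
# 30 uM GABA: pIC50 (with SEM) and the printed IC50, for inhibition of the
# peak current, the 20-s steady-state current, and for acceleration of the
# current decay. NA marks potencies the source reports as not measurable;
# the compound-5 peak entry is a graphical extrapolation ("est.").
compound,peak_pic50,peak_pic50_sem,peak_ic50_uM,steady_pic50,steady_pic50_sem,steady_ic50_uM,decay_pic50,decay_pic50_sem,decay_ic50_uM
2,5.577,0.140,2.7,6.555,0.058,0.28,6.058,0.078,0.88
3,3.129,0.688,743,6.050,0.149,0.89,5.070,0.170,8.5
4,NA,NA,NA,5.265,0.085,5.4,3.663,0.186,217
5,2.7,NA,2000,6.074,0.054,0.84,3.933,0.194,117
6,3.658,0.243,220,5.946,0.188,1.1,5.781,0.047,1.7
7,4.327,0.128,47,6.391,0.038,0.41,5.142,0.087,7.2
8,4.478,0.128,33,6.627,0.025,0.24,5.491,0.115,3.2
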