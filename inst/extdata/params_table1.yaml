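# Packaged default parameter set of the coptisine/LPS PK-PD model
# (population estimates of the published final model).
# Units: V1 mL/animal; k0 phases and Vm pg/(mL*h); km pg/mL; InhibitCon
# mL/ng; w1, w2 h; delta dimensionless; other rate constants 1/h.
V1: 2630.0
k10: 0.458
k12: 2.05
k21: 0.668
k13: 0.0121
k31: 3.77
k0_phase1: 645.73
k0_phase2: 5881.32
w1: 0.333
w2: 0.667
InhibitCon: 8.83e-4
Vm: 5990.0
km: 5180.0
k_TNFapl: 3.54e-7
k_outTNFa: 0.234
k_iNOSmRNA: 3.38e-3
k_outiNOSmRNA: 2.36
k_iNOS: 0.299
k_outiNOS: 3.72
k_iNOSlp: 23.41
k_outiNOSp: 1.92
k_iNOSNO: 772.17
delta: 1.23
k_inNO: 354.68
k_outNO: 3.46
sigma_add:
  cop_plasma: 25.0
  cop_lung: 0.08
  tnfa_plasma: 80.0
  tnfa_lung: 2.5e-5
  inos_lung: 2.5e-9
  no_plasma: 2.5e-7
omega:
  V1: 0.2
  k10: 0.2
  k12: 0.2
  k21: 0.2
  k13: 0.2
  k31: 0.2
  k0_phase1: 0.2
  k0_phase2: 0.2
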