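# Diabetes mellitus: dilated capillaries (+14% diameter), thickened GBM
name: dm
R_AA: 2.2e10
R_EA: 1.0e10
C_A: 5.9
t_bm_nm: 162
p_BS: 11
MAP: 117
p_e: 13
diameter_scale: 1.14
targets:
  P_GC: 63
  Q_A: 268
  SNGFR: 81.6
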