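# Control animals paired with the diabetes condition
name: zatz_control
R_AA: 4.7e10
R_EA: 1.3e10
C_A: 5.6
t_bm_nm: 138
p_BS: 13
MAP: 119
p_e: 13
diameter_scale: 1.0
targets:
  P_GC: 52
  Q_A: 154
  SNGFR: 45.9
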