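# Control animals paired with the 5/6-nephrectomy condition
name: kasiske_control
R_AA: 7.2e10
R_EA: 1.8e10
C_A: 5.2
t_bm_nm: 149.82
p_BS: 13
MAP: 124
p_e: 13
diameter_scale: 1.0
targets:
  P_GC: 51
  Q_A: 112
  SNGFR: 35.5
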