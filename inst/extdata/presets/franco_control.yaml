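# Control animals paired with the angiotensin II hypertension condition
name: franco_control
R_AA: 5.9e10
R_EA: 1.5e10
C_A: 5.12
t_bm_nm: 149.82
p_BS: 11
MAP: 115
p_e: 13
diameter_scale: 1.0
targets:
  P_GC: 49
  Q_A: 122
  SNGFR: 36.2
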