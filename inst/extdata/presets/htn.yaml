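# Angiotensin II-induced hypertension: constricted arterioles, no remodeling
name: htn
R_AA: 16.1e10
R_EA: 2.7e10
C_A: 5.49
t_bm_nm: 149.82
p_BS: 13
MAP: 165
p_e: 13
diameter_scale: 1.0
targets:
  P_GC: 55
  Q_A: 76
  SNGFR: 23.1
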