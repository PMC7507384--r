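# Base-case operating point (normal Sprague-Dawley rat)
name: base
R_AA: 5.5e10   # dyn s/cm^5
R_EA: 1.0e10
C_A: 5.94      # g/dl
t_bm_nm: 149.82
p_BS: 13       # mmHg
MAP: 115
p_e: 13
diameter_scale: 1.0
targets:
  P_GC: 50     # mmHg
  Q_A: 129     # nl/min afferent plasma flow
  SNGFR: 30    # nl/min
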