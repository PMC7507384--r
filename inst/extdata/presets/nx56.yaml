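# Remnant glomerulus 4 weeks post 5/6-nephrectomy: +23% diameters, GBM unchanged
name: nx56
R_AA: 2.9e10
R_EA: 0.8e10
C_A: 5.3
t_bm_nm: 146.99
p_BS: 12
MAP: 138
p_e: 13
diameter_scale: 1.23
targets:
  P_GC: 57
  Q_A: 309
  SNGFR: 97.0
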