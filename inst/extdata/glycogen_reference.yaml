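model: glycogen_params
units: uM, min
parameters:
  vmax_phk: 5.0
  km_phk: 10.0
  ki_drug: 5.5
  vmax_pp1: 5.0
  km_pp1: 10.0
  k_gs_inact: 1.0
  vmax_gp: 0.6
  km_gp_gly: 5000.0
  vmax_gs: 0.8
  km_gs_g6p: 100.0
  k_g6p_in: 10.0
  k_g6p_out: 0.1
  gp_total: 10.0
  gs_total: 10.0
  gly_cap: 20000.0
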