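model: ppp_params
units: uM, min
parameters:
  vmax_g6pd: 50.0
  km_g6pd_g6p: 100.0
  km_g6pd_nadp: 10.0
  vmax_6pgd: 50.0
  km_6pgd_6pg: 20.0
  km_6pgd_nadp: 10.0
  k_nadph_drain: 1.0
  k_g6p_refresh: 1.0
  nadp_total: 100.0
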