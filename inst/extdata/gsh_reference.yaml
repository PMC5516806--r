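model: gsh_params
units: uM, min
parameters:
  k_h2o2_prod: 2.0
  vmax_gpx: 50.0
  km_gpx_gsh: 100.0
  km_gpx_h2o2: 1.0
  vmax_gr: 16.0
  km_gr_gssg: 20.0
  km_gr_nadph: 100.0
  k_nadph_supply: 5.0
  k_synth: 0.0
  k_efflux: 0.0
  k_vite_quench: 0.1
  vite_pool: 0.0
  nadp_total: 100.0
  gsh_total_init: 200.0
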