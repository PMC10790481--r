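{
  "EX_glc__D_e": 10,
  "EX_o2_e": 18.5,
  "EX_nh4_e": 1000,
  "EX_pi_e": 1000,
  "EX_so4_e": 1000,
  "EX_h2o_e": 1000,
  "EX_h_e": 1000,
  "EX_k_e": 1000,
  "EX_na1_e": 1000,
  "EX_mg2_e": 1000,
  "EX_ca2_e": 1000,
  "EX_cl_e": 1000,
  "EX_fe2_e": 1000,
  "EX_fe3_e": 1000,
  "EX_cu2_e": 1000,
  "EX_mn2_e": 1000,
  "EX_zn2_e": 1000,
  "EX_cobalt2_e": 1000,
  "EX_mobd_e": 1000,
  "EX_ni2_e": 1000,
  "EX_sel_e": 1000,
  "EX_tungs_e": 1000,
  "EX_slnt_e": 1000
}
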