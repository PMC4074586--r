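# Glucose minimal medium for BiGG-namespace E. coli reconstructions.
# Uptake limits are positive magnitudes (mmol/gDW/h); .inf = unbounded.
# Glucose is capped at 10; oxygen is toggled by glucose_minimal_medium().
exchanges:
  EX_glc__D_e: {uptake: 10}
  EX_o2_e: {uptake: .inf}
  EX_nh4_e: {uptake: .inf}
  EX_pi_e: {uptake: .inf}
  EX_so4_e: {uptake: .inf}
  EX_k_e: {uptake: .inf}
  EX_na1_e: {uptake: .inf}
  EX_mg2_e: {uptake: .inf}
  EX_ca2_e: {uptake: .inf}
  EX_cl_e: {uptake: .inf}
  EX_fe2_e: {uptake: .inf}
  EX_fe3_e: {uptake: .inf}
  EX_cu2_e: {uptake: .inf}
  EX_mn2_e: {uptake: .inf}
  EX_zn2_e: {uptake: .inf}
  EX_ni2_e: {uptake: .inf}
  EX_cobalt2_e: {uptake: .inf}
  EX_mobd_e: {uptake: .inf}
  EX_sel_e: {uptake: .inf}
  EX_slnt_e: {uptake: .inf}
  EX_tungs_e: {uptake: .inf}
  EX_cbl1_e: {uptake: 0.01}
  EX_h_e: {uptake: .inf}
  EX_h2o_e: {uptake: .inf}
  EX_co2_e: {uptake: .inf}
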