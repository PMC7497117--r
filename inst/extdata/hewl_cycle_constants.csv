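quantity,value,error
dg_coul_l,-142.8,1.7
dg_lj_l,-9.1,6.3
dg_restr_off,-31.3,0
annihilation_lig_espp,-1275.3,11.2
annihilation_compl_espp,1315.2,16.3
annihilation_lig_grom,-1259.0,5.9
annihilation_compl_grom,1314.8,13.2
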