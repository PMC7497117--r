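label,n_at,dg_coul_c,err_coul_c,dg_lj_c,err_lj_c,dg_restr_on_c,err_restr_on_c
fully-at,NA,145.2,3.5,44.2,5.2,3.6,0.4
aa-3,3,125.5,7.0,50.4,6.3,8.3,1.1
aa-4,4,141.4,4.9,39.7,9.4,7.2,1.0
aa-5,5,140.2,2.8,48.7,4.5,7.5,1.2
aa-6,6,147.0,1.9,41.7,5.4,5.1,0.5
aa-7,7,144.5,0.8,38.4,3.8,5.0,0.2
aa-8,8,148.0,1.4,33.6,1.9,6.4,1.8
aa-9,9,143.4,4.7,38.1,5.3,5.1,0.3
aa-10,10,145.9,2.2,38.2,1.0,4.4,0.3
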