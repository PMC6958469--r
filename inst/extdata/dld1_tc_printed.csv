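model,ttc_kbq_kg,olaparib_mg_kg,t_over_c,p_label
parental,125,0,0.9,n.s.
parental,300,0,0.5,p = 0.03
parental,600,0,0.3,p < 0.0001
parental,0,25,0.6,n.s.
parental,0,50,0.6,n.s.
parental,125,25,0.8,n.s.
parental,125,50,0.6,n.s.
parental,300,25,0.4,p < 0.0001
parental,300,50,0.5,p = 0.009
brca2ko,125,0,0.8,n.s.
brca2ko,300,0,0.5,p < 0.0001
brca2ko,600,0,0.1,p < 0.0001
brca2ko,0,25,0.4,p < 0.0001
brca2ko,0,50,0.5,p < 0.0001
brca2ko,125,25,0.4,p < 0.0001
brca2ko,125,50,0.1,p < 0.0001
brca2ko,300,25,0.2,p < 0.0001
brca2ko,300,50,0.03,p < 0.0001
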