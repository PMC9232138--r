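# HT phenotype (higher ethanol tolerance) ethanol-stress constraint set.
Sic1[0,2]
Cdh1[0,2]
Mih1[0,1]
Clb1_2[0,2]
SCF_Cdc4^
Cln3[0,2]
Cln1_2[0,2]
Swe1[0,1]
Cdc20[0,2]
Clb5_6[0,2]
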