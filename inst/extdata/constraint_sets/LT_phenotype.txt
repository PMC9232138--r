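# LT phenotype (lower ethanol tolerance) ethanol-stress constraint set,
# derived from the phenotype-level expression profile of the ten selected
# cell-cycle genes. One constraint per line.
Sic1[0,1]
Cdh1[0,1]
Mih1!
Clb1_2^
SCF_Cdc4[0,2]
Cln3[0,2]
Cln1_2[0,2]
Swe1[0,2]
Cdc20[0,2]
Clb5_6[0,2]
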