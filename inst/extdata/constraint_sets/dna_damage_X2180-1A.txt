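# DNA-damage checkpoint constraint set (HT strain X2180-1A): MEC1 and RAD53
# downregulated, PDS1 downregulated, CHK1 not differentially expressed.
Mec1[0,1]
Chk1[0,2]
Rad53[0,1]
Pds1[0,1]
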