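# DNA-damage checkpoint constraint set (HT strain BY4742): MEC1 and CHK1
# upregulated (regulator clamps), RAD53 and PDS1 downregulated.
Mec1[DNA_Damage@2]
Chk1[Mec1@2]
Rad53[0,1]
Pds1[0,1]
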