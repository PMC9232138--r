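# DNA-damage checkpoint constraint set (LT strain): MEC1, CHK1 and RAD53 are
# upregulated, encoded as regulator clamps at the arrest level.
Mec1[DNA_Damage@2]
Chk1[Mec1@2]
Rad53[Mec1@2]
Pds1[0,2]
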