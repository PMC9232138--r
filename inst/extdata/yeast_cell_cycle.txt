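# logic model: yeast_cell_cycle
# nodes: 67  interactions: 144
node MASS max=2 class=phenomenological
  when MITOSIS_EXIT == 2 -> 0
  when MASS == 0 -> 1
  when TRUE -> 2
node BUD max=2 class=phenomenological
  when MITOSIS_EXIT == 2 -> 0
  when BUD >= 1 -> 2
  when (Cln1_2 >= 2 | Clb5_6 >= 2) & MASS == 2 -> 2
node DNA_Replication max=1 class=phenomenological
  when MITOSIS_EXIT == 2 -> 0
  when DNA_Replication == 1 -> 1
  when pre_RC >= 2 & Clb5_6 >= 2 & Cdc45 >= 2 -> 1
node Spindle max=2 class=phenomenological
  when MITOSIS_EXIT == 2 -> 0
  when Spindle >= 1 & DNA_Replication == 1 -> 2
  when Clb3_4 >= 2 & DNA_Replication == 1 -> 2
node MITOSIS_EXIT max=2 class=phenomenological
  when MITOSIS_EXIT == 2 & MASS > 0 -> 2
  when MITOSIS_EXIT == 1 & Clb1_2 == 0 & Spindle == 2 -> 2
  when BUD == 2 & DNA_Replication == 1 & Spindle == 2 & Clb1_2 >= 2 -> 1
  when MITOSIS_EXIT == 1 & DNA_Replication == 1 -> 1
node Mating max=1 class=checkpoint
node Unattached_Kinetochores max=2 class=checkpoint
  when Unattached_Kinetochores == 2 & Spindle < 2 -> 2
node Misaligned_Spindle max=2 class=checkpoint
  when Misaligned_Spindle == 2 & Spindle < 2 -> 2
node DNA_Damage max=2 class=checkpoint
  when DNA_Damage == 2 -> 2
node SCB max=3 class=regulatory_element
  when SBF >= 2 -> 2
  when SBF == 1 -> 1
node ECB max=3 class=regulatory_element
  when Mcm1 >= 1 -> 2
node MCB max=3 class=regulatory_element
  when MBF >= 2 -> 2
  when MBF == 1 -> 1
node ARS max=3 class=regulatory_element
  when ORC >= 2 -> 2
node S_proteins max=3 class=complex
  when MCB >= 2 -> 2
node G2_proteins max=3 class=complex
  when DNA_Replication == 1 & MITOSIS_EXIT < 2 -> 3
node lnc9136 max=3 class=gene_or_lncRNA
node lnc10883 max=3 class=gene_or_lncRNA
node Mec1 max=2 class=protein
  when DNA_Damage == 2 -> 2
  when DNA_Damage == 1 -> 1
node Chk1 max=2 class=protein
  when Mec1 == 2 -> 2
  when Mec1 == 1 -> 1
node Rad53 max=2 class=protein
  when Mec1 == 2 -> 2
  when Mec1 == 1 -> 1
node Bub1 max=2 class=protein
  when Unattached_Kinetochores == 2 | Misaligned_Spindle == 2 | Mps1 == 2 -> 2
  when Unattached_Kinetochores == 1 | Misaligned_Spindle == 1 -> 1
node Mps1 max=2 class=protein
  when Unattached_Kinetochores == 2 -> 2
  when Unattached_Kinetochores == 1 -> 1
node Bub3 max=2 class=protein
  when Bub1 == 2 -> 2
  when Bub1 == 1 -> 1
node Mad3 max=2 class=protein
  when Bub1 == 2 -> 2
  when Bub1 == 1 -> 1
node Mad1_Mad2 max=2 class=complex
  when Bub1 == 2 -> 2
  when Bub1 == 1 -> 1
node MCC max=2 class=complex
  when Mad3 == 2 & Bub3 == 2 & Mad1_Mad2 == 2 -> 2
  when Mad3 >= 1 & Bub3 >= 1 & Mad1_Mad2 >= 1 -> 1
node Bfa1_Bub2 max=2 class=complex
  when Misaligned_Spindle == 2 & Bub1 >= 1 -> 2
  when Misaligned_Spindle == 1 -> 1
node Far1 max=1 class=protein
  when Mating == 1 & Fus3 == 1 -> 1
node Fus3 max=1 class=protein
  when Mating == 1 -> 1
node Cln3 max=3 class=protein
  when Far1 == 1 -> 0
  when ECB >= 1 & MASS == 2 -> 2
node Cln1_2 max=3 class=protein
  when Far1 == 1 -> 0
  when SCB >= 1 -> 2
node Clb5_6 max=3 class=protein
  when Sic1 >= 2 -> 0
  when MCB >= 2 -> 2
node Clb3_4 max=3 class=protein
  when G2_proteins >= 2 & MCB >= 1 -> 2
node Clb1_2 max=3 class=protein
  when (APCC_Cdc20 >= 2 | APCC_Cdh1 >= 2) & (Sic1 >= 2 | Swe1 >= 2) -> 0
  when (APCC_Cdc20 >= 2 | APCC_Cdh1 >= 2) & Cdc14 == 3 & Clb1_2 <= 2 -> 0
  when Clb1_2 == 3 & G2_proteins >= 1 -> 3
  when Swe1 >= 2 & Mih1 == 0 & Clb1_2 <= 1 -> 0
  when G2_proteins == 3 & MCB >= 1 & Cak1 == 1 -> 2
  when Clb1_2 >= 1 & G2_proteins >= 1 -> 2
node SBF max=3 class=complex
  when Clb1_2 >= 2 -> 0
  when Cln1_2 >= 2 | Cln3 >= 2 -> 2
  when ECB >= 2 -> 1
node MBF max=3 class=complex
  when Cln1_2 >= 2 | (Cln3 >= 2 & Whi5 == 0) -> 2
  when Cln3 >= 2 -> 1
node Mcm1 max=3 class=protein
  when MASS == 2 -> 2
node Swi5 max=3 class=protein
  when Cdc14 == 3 & Clb1_2 <= 1 -> 2
node Whi5 max=3 class=protein
  when Cln3 >= 2 -> 0
  when TRUE -> 2
node Cdc45 max=3 class=protein
  when S_proteins >= 2 & Cdc7_Dbf4 >= 2 -> 2
node Tah11 max=3 class=protein
  when MBF >= 2 -> 2
node Cdc6 max=3 class=protein
  when SCF_Cdc4 == 3 -> 0
  when ECB >= 2 & Spindle == 0 -> 2
node MCM max=3 class=protein
  when Cdc6 >= 2 & Tah11 >= 2 -> 2
node ORC max=3 class=protein
  when TRUE -> 2
node pre_RC max=3 class=complex
  when DNA_Replication == 1 -> 0
  when ORC >= 2 & Cdc6 >= 2 & Tah11 >= 2 & MCM >= 2 & ARS >= 2 -> 2
  when ORC >= 1 & Cdc6 >= 1 & Tah11 >= 1 & MCM >= 1 & ARS >= 1 -> 1
node Cdc7_Dbf4 max=3 class=complex
  when S_proteins >= 2 -> 2
node Sic1 max=3 class=protein
  when SCF_Cdc4 >= 2 & (Cln1_2 >= 2 | Cln3 >= 2) -> 0
  when Swi5 >= 2 | Cdc14 == 3 -> 3
  when Sic1 >= 1 -> 2
node SCF_Cdc4 max=3 class=complex
  when SCF_Cdc4 == 3 -> 3
  when Cln1_2 >= 1 | Cln3 >= 2 -> 2
node Swe1 max=3 class=protein
  when Hsl1 >= 2 & Cdc5 >= 2 -> 0
  when Gin4 >= 2 | Hsl1 >= 2 -> 1
  when G2_proteins >= 1 -> 2
node Mih1 max=1 class=protein
  when G2_proteins >= 2 -> 1
node Cak1 max=1 class=protein
  when TRUE -> 1
node Hsl1 max=3 class=protein
  when DNA_Replication == 1 -> 3
node Gin4 max=3 class=protein
  when DNA_Replication == 1 -> 3
node Kcc4 max=3 class=protein
  when DNA_Replication == 1 -> 1
node Cdc5 max=3 class=protein
  when Rad53 == 2 -> 0
  when Clb1_2 >= 1 -> 2
node Cdc20 max=3 class=protein
  when Clb1_2 >= 2 -> 2
node Cdh1 max=3 class=protein
  when Cdc14 >= 2 & Clb1_2 <= 1 -> 3
  when Cdh1 >= 1 & Clb1_2 == 0 -> 2
node APCC_Cdc20 max=3 class=complex
  when MCC == 2 -> 0
  when Cdc20 >= 2 & Clb1_2 >= 2 & Cdc5 >= 2 -> 2
  when Cdc20 >= 1 & Clb1_2 >= 1 -> 1
node APCC_Cdh1 max=3 class=complex
  when Cdh1 >= 2 -> 2
node Cdc14 max=3 class=protein
  when Net1 == 0 & Dbf2_Mob1 >= 2 -> 3
  when Net1 == 0 -> 2
node Net1 max=3 class=protein
  when (Esp1 >= 2 & Cdc5 >= 2) | Dbf2_Mob1 >= 2 -> 0
  when TRUE -> 2
node Esp1 max=3 class=protein
  when Pds1 <= 1 & Spindle == 2 -> 2
node Pds1 max=3 class=protein
  when Chk1 == 2 -> 3
  when APCC_Cdc20 >= 2 -> 0
  when G2_proteins >= 1 -> 2
node Tem1 max=3 class=protein
  when Bfa1_Bub2 == 2 -> 0
  when Esp1 >= 2 & (Lte1 >= 2 | Spindle == 2) -> 2
node Cdc15 max=3 class=protein
  when Tem1 >= 2 -> 2
node Dbf2_Mob1 max=3 class=complex
  when Cdc15 >= 2 & Cdc5 >= 2 -> 2
node Lte1 max=3 class=protein
  when BUD == 2 & G2_proteins >= 1 -> 2
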