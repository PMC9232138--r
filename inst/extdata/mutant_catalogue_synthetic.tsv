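# Synthetic reconstruction of a 109-entry budding-yeast cell-cycle mutant
# benchmark: knockout/overexpression perturbations of model nodes paired with
# the phenotype reported in the classical genetics literature for the
# corresponding mutant or allele. Perturbation notation: Node! = knockout
# (fix 0), Node=v = fix at level v; multiple perturbations are
# space-separated. Reported phenotypes: viable, inviable, or
# "arrest in G1/S/G2/M".
mutant_id	perturbation	reported
cln3d	Cln3!	viable
cln1d_cln2d	Cln1_2!	viable
cln1d_cln2d_cln3d	Cln3! Cln1_2!	inviable
whi5d	Whi5!	viable
WHI5_ox	Whi5=3	viable
swi4d	SBF!	viable
swi4d_swi6d	SBF! MBF!	inviable
sic1d	Sic1!	viable
SIC1_ox	Sic1=3	arrest in G1
cdc4_ts	SCF_Cdc4!	arrest in G1
cdc6_1	Cdc6!	inviable
orc1_ts	ORC!	inviable
mcm2_ts	MCM!	inviable
tah11_td	Tah11!	inviable
cdc45_1	Cdc45!	arrest in S
cdc7_4	Cdc7_Dbf4!	arrest in S
clb5d_clb6d	Clb5_6!	viable
clb3d_clb4d	Clb3_4!	viable
clb1d_clb2d	Clb1_2!	inviable
cak1d	Cak1!	inviable
swe1d	Swe1!	viable
SWE1_ox	Swe1=3	arrest in G2
mih1d	Mih1!	viable
hsl1d	Hsl1!	viable
gin4d	Gin4!	viable
kcc4d	Kcc4!	viable
hsl1d_gin4d	Hsl1! Gin4!	viable
hsl1d_gin4d_kcc4d	Hsl1! Gin4! Kcc4!	viable
cdc5_ts	Cdc5!	inviable
CDC5_ox	Cdc5=3	viable
cdc20_ts	Cdc20!	arrest in M
CDC20_ox	Cdc20=3	viable
cdh1d	Cdh1!	viable
sic1d_cdh1d	Sic1! Cdh1!	inviable
esp1_td	Esp1!	arrest in M
pds1d	Pds1!	viable
PDS1_ox_stable	Pds1=3	arrest in M
cdc14_ts	Cdc14!	arrest in M
CDC14_ox	Cdc14=3	arrest in G1
cdc15_ts	Cdc15!	arrest in M
tem1_ts	Tem1!	arrest in M
dbf2d_mob1ts	Dbf2_Mob1!	arrest in M
net1d	Net1!	viable
NET1_ox	Net1=3	arrest in M
lte1d	Lte1!	viable
bfa1d_bub2d	Bfa1_Bub2!	viable
BFA1_ox	Bfa1_Bub2=2	arrest in M
mcm1_ts	Mcm1!	inviable
swi5d	Swi5!	viable
far1d	Far1!	viable
fus3d	Fus3!	viable
FAR1_ox	Far1=1	arrest in G1
bub1d	Bub1!	viable
bub3d	Bub3!	viable
mad3d	Mad3!	viable
mad1d_mad2d	Mad1_Mad2!	viable
mps1_1	Mps1!	inviable
MPS1_ox	Mps1=2	arrest in M
mec1d_sml1d	Mec1!	viable
rad53d_sml1d	Rad53!	viable
chk1d	Chk1!	viable
CLN3_ox	Cln3=3	viable
CLN2_ox	Cln1_2=3	viable
CLB5_ox	Clb5_6=3	viable
CLB2_ox_stable	Clb1_2=3	arrest in M
MAD2_ox	MCC=2	arrest in M
swe1d_mih1d	Swe1! Mih1!	viable
far1d_fus3d	Far1! Fus3!	viable
bub1d_mad3d	Bub1! Mad3!	viable
bub3d_mad1d	Bub3! Mad1_Mad2!	viable
pds1d_esp1td	Pds1! Esp1!	inviable
CDC6_ox	Cdc6=3	viable
CDC15_ox	Cdc15=3	viable
TEM1_ox	Tem1=3	viable
whi5d_cln3d	Whi5! Cln3!	viable
CLB5_ox_sic1d	Clb5_6=3 Sic1!	viable
bub1d_bub3d	Bub1! Bub3!	viable
mad1d_mad3d	Mad1_Mad2! Mad3!	viable
mec1d_rad53d	Mec1! Rad53!	viable
chk1d_rad53d	Chk1! Rad53!	viable
MCM1_ox	Mcm1=3	viable
orc2_1	ORC!	inviable
mcm3_ts	MCM!	inviable
cdc6_4	Cdc6!	inviable
cdc45_27	Cdc45!	inviable
cdc7_1	Cdc7_Dbf4!	inviable
cdc15_2	Cdc15!	inviable
cdc14_1	Cdc14!	inviable
cdc5_1	Cdc5!	arrest in M
cdc20_1	Cdc20!	inviable
esp1_1	Esp1!	inviable
tem1_3	Tem1!	inviable
dbf2_2	Dbf2_Mob1!	inviable
mob1_77	Dbf2_Mob1!	inviable
cak1_ts	Cak1!	arrest in G2
clb1d_clb2ts	Clb1_2!	arrest in G2
cdc4_1	SCF_Cdc4!	inviable
cdc53_1	SCF_Cdc4!	inviable
skp1_11	SCF_Cdc4!	arrest in G1
skp1_12	SCF_Cdc4!	arrest in G2
GAL_CLB2_dbD	Clb1_2=3	arrest in M
swi6_ts	MBF!	viable
SIC1_4A_stable	Sic1=3	arrest in G1
cdh1d_pds1d	Cdh1! Pds1!	viable
net1_1	Net1!	viable
GAL_ESP1	Esp1=3	viable
MAD1_ox	Mad1_Mad2=2	arrest in M
gin4d_kcc4d	Gin4! Kcc4!	viable
hsl1d_kcc4d	Hsl1! Kcc4!	viable
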