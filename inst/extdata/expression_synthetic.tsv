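# Synthetic log2 fold-change table (treatment vs control at each strain's
# highest tolerated ethanol level) for the cell-cycle genes used to build
# model constraints. Phenotype-level rows (LT, HT) cover the ten selected
# cell-cycle genes shared within each tolerance phenotype; strain-level rows
# cover the DNA-damage checkpoint genes; the two lncRNA rows carry the
# published fold-changes (lnc9136 = 1.25 in SEY6210, lnc10883 = 1.4 in
# BY4742). log2fc = 0 marks non-differentially-expressed genes;
# significant = FDR < 0.01.
phenotype_or_strain	gene	log2fc	significant
LT	SIC1	-1.2	TRUE
LT	CDH1	-0.9	TRUE
LT	MIH1	-1.5	TRUE
LT	CLB2	1.1	TRUE
LT	CDC4	0	FALSE
LT	CLN3	0	FALSE
LT	CLN2	0	FALSE
LT	SWE1	0	FALSE
LT	CDC20	0	FALSE
LT	CLB5	0	FALSE
HT	SIC1	0	FALSE
HT	CDH1	0	FALSE
HT	MIH1	0	FALSE
HT	CLB2	0	FALSE
HT	CDC4	1.3	TRUE
HT	CLN3	0	FALSE
HT	CLN2	0	FALSE
HT	SWE1	-0.6	TRUE
HT	CDC20	0	FALSE
HT	CLB5	0	FALSE
S288C	MEC1	1.1	TRUE
S288C	CHK1	0.9	TRUE
S288C	RAD53	0.8	TRUE
S288C	PDS1	0	FALSE
BY4741	MEC1	0.9	TRUE
BY4741	CHK1	0.7	TRUE
BY4741	RAD53	1.2	TRUE
BY4741	PDS1	0	FALSE
SEY6210	MEC1	1.3	TRUE
SEY6210	CHK1	1.1	TRUE
SEY6210	RAD53	0.6	TRUE
SEY6210	PDS1	0	FALSE
SEY6210	lnc9136	1.25	TRUE
X2180-1A	MEC1	-0.8	TRUE
X2180-1A	CHK1	0	FALSE
X2180-1A	RAD53	-1.1	TRUE
X2180-1A	PDS1	-0.5	TRUE
BY4742	MEC1	1.2	TRUE
BY4742	CHK1	0.9	TRUE
BY4742	RAD53	-1.0	TRUE
BY4742	PDS1	-0.7	TRUE
BY4742	lnc10883	1.4	TRUE
BMA64-1A	PDS1	0.4	TRUE
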