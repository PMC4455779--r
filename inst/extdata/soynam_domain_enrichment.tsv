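domain	description	genome_genes	obs_downcnv_pav
CL0022	Leucine-rich repeat	1110	168
PF07714	Protein tyrosine kinase	786	38
PF08263	Leucine-rich repeat N-terminal domain	550	74
PF00931	NB-ARC domain	454	112
PF01582	Toll-interleukin receptor	196	30
PF14368	Probable lipid transfer	104	14
PF12819	Carbohydrate-binding protein of the ER	95	14
PF14111	Domain of unknown function (DUF4283)	82	10
PF13947	Wall-associated receptor kinase galacturonan-binding	71	10
PF14380	Wall-associated receptor kinase C-terminal	33	10
PF05686	Glycosyl transferase family 90	20	7
PF05018	Domain of unknown function (DUF667)	7	5
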