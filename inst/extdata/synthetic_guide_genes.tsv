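role	gene_id
PAL1	guide_PAL1
PAL2	guide_PAL2
C4H	guide_C4H
4CL	guide_4CL
CHS1	guide_CHS1
CHS2	guide_CHS2
CHI	guide_CHI
F3H	guide_F3H
F3pH	guide_F3pH
FLS	guide_FLS
DFR	guide_DFR
LAR	guide_LAR
ANR	guide_ANR
ANS	guide_ANS
UFGT	guide_UFGT
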