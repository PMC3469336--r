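# Common palindromic restriction enzymes (forward-strand recognition,
# cut_offset = bases into the site before the cut)
name	recognition	cut_offset
NcoI	CCATGG	1
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
PstI	CTGCAG	5
TaqI	TCGA	1
AluI	AGCT	2
HpaII	CCGG	1
DraI	TTTAAA	3
AvaII	GGWCC	1
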