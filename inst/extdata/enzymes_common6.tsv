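name	site	common
EcoRI	GAATTC	TRUE
BamHI	GGATCC	TRUE
HindIII	AAGCTT	TRUE
DraI	TTTAAA	TRUE
EcoRV	GATATC	TRUE
XbaI	TCTAGA	TRUE
PstI	CTGCAG	TRUE
SmaI	CCCGGG	TRUE
KpnI	GGTACC	TRUE
SacI	GAGCTC	TRUE
SalI	GTCGAC	TRUE
SphI	GCATGC	TRUE
XhoI	CTCGAG	TRUE
NcoI	CCATGG	TRUE
NdeI	CATATG	TRUE
BglII	AGATCT	TRUE
ScaI	AGTACT	TRUE
SspI	AATATT	TRUE
HpaI	GTTAAC	TRUE
StuI	AGGCCT	TRUE
AvaI	CYCGRG	TRUE
HincII	GTYRAC	TRUE
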