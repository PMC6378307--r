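id	class	symbol	formula	charge	gibbs_energy	gibbs_units	source
Ala	amino_acid	A	C3H7NO2	0	-371.7	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Arg	amino_acid	R	C6H14N4O2	0	-240.2	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Asn	amino_acid	N	C4H8N2O3	0	-525.9	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Asp	amino_acid	D	C4H7NO4	0	-721.5	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Cys	amino_acid	C	C3H7NO2S	0	-340.0	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Gln	amino_acid	Q	C5H10N2O3	0	-524.6	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Glu	amino_acid	E	C5H9NO4	0	-723.8	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Gly	amino_acid	G	C2H5NO2	0	-380.8	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
His	amino_acid	H	C6H9N3O2	0	-236.7	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Ile	amino_acid	I	C6H13NO2	0	-345.0	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Leu	amino_acid	L	C6H13NO2	0	-352.3	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Lys	amino_acid	K	C6H14N2O2	0	-336.9	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Met	amino_acid	M	C5H11NO2S	0	-506.6	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Phe	amino_acid	F	C9H11NO2	0	-207.1	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Pro	amino_acid	P	C5H9NO2	0	-305.0	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Ser	amino_acid	S	C3H7NO3	0	-518.6	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Thr	amino_acid	T	C4H9NO3	0	-513.9	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Trp	amino_acid	W	C11H12N2O2	0	-112.6	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Tyr	amino_acid	Y	C9H11NO3	0	-385.7	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
Val	amino_acid	V	C5H11NO2	0	-358.2	kJ/mol	approx. Amend & Helgeson (1997) / Dick et al. (2006)
adenine	nucleobase	A	C5H5N5	0	307.6	kJ/mol	approx. LaRowe & Helgeson (2006)
cytosine	nucleobase	C	C4H5N3O	0	-74.7	kJ/mol	approx. LaRowe & Helgeson (2006)
guanine	nucleobase	G	C5H5N5O	0	47.9	kJ/mol	approx. LaRowe & Helgeson (2006)
thymine	nucleobase	T	C5H6N2O2	0	-317.6	kJ/mol	approx. LaRowe & Helgeson (2006)
uracil	nucleobase	U	C4H4N2O2	0	-297.2	kJ/mol	approx. LaRowe & Helgeson (2006)
ribose	sugar	NA	C5H10O5	0	-757.3	kJ/mol	approx. LaRowe & Helgeson (2006)
deoxyribose	sugar	NA	C5H10O4	0	-601.3	kJ/mol	approx. LaRowe & Helgeson (2006)
dA	deoxyribonucleoside	A	C10H13N5O3	0	-31.5	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
dC	deoxyribonucleoside	C	C9H13N3O4	0	-413.8	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
dG	deoxyribonucleoside	G	C10H13N5O4	0	-291.2	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
dT	deoxyribonucleoside	T	C10H14N2O5	0	-656.7	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
rA	ribonucleoside	A	C10H13N5O4	0	-187.5	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
rC	ribonucleoside	C	C9H13N3O5	0	-569.8	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
rG	ribonucleoside	G	C10H13N5O5	0	-447.2	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
rU	ribonucleoside	U	C9H12N2O6	0	-792.3	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate
rT	ribonucleoside	T	C10H14N2O6	0	-812.7	kJ/mol	approx. LaRowe & Helgeson (2006); additive estimate (hypothetical T-bearing RNA)
dAMP	nmp_dna	A	C10H12N5O6P-2	-2	-871.4	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion ("+2" in text read as sign typo)
dCMP	nmp_dna	C	C9H12N3O7P-2	-2	-1253.7	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion ("+2" in text read as sign typo)
dGMP	nmp_dna	G	C10H12N5O7P-2	-2	-1131.1	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion ("+2" in text read as sign typo)
dTMP	nmp_dna	T	C10H13N2O8P-2	-2	-1496.6	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion ("+2" in text read as sign typo)
rAMP	nmp_rna	A	C10H12N5O7P-2	-2	-1027.4	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion
rCMP	nmp_rna	C	C9H12N3O8P-2	-2	-1409.7	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion
rGMP	nmp_rna	G	C10H12N5O8P-2	-2	-1287.1	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion
rUMP	nmp_rna	U	C9H11N2O9P-2	-2	-1632.2	kJ/mol	approx. LaRowe & Helgeson (2006); 2- ion
H2O	basis	NA	H2O	0	-237.2	kJ/mol	CODATA
HCO3	basis	NA	HCO3-	-1	-586.9	kJ/mol	CODATA
H2PO4	basis	NA	H2PO4-	-1	-1130.3	kJ/mol	CODATA
NH4	basis	NA	NH4+	1	-79.4	kJ/mol	CODATA
HS	basis	NA	HS-	-1	12.2	kJ/mol	CODATA
H+	basis	NA	H+	1	0	kJ/mol	convention
e-	basis	NA	e-	-1	0	kJ/mol	convention
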