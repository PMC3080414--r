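complex	res_seq	res_name	atom	ligand_atom	distance	contact_class	flagged
cGMP	182	GLY	N	O2'	3.0	hydrogen_bond	FALSE
cGMP	183	GLU	OE1	O2'	2.2	hydrogen_bond	FALSE
cGMP	185	ALA	N	O1P	3.2	hydrogen_bond	FALSE
cGMP	192	ARG	NH1	O1P	2.8	hydrogen_bond	FALSE
cGMP	193	THR	N	O2P	2.8	hydrogen_bond	FALSE
cGMP	193	THR	OG1	O2P	2.7	hydrogen_bond	FALSE
cGMP	193	THR	OG1	N2	2.8	hydrogen_bond	FALSE
cGMP	165	VAL	CG1	C5	3.9	vdw	FALSE
cGMP	172	LEU	CD(min)	N1	3.2	vdw	FALSE
cGMP	172	LEU	CD(min)	O6	3.1	vdw	FALSE
cGMP	173	CYS	SG	N7	3.5	vdw	FALSE
cGMP	175	MET	CE	C8	3.9	vdw	FALSE
syn-cAMP	182	GLY	N	O2'	2.9	hydrogen_bond	FALSE
syn-cAMP	183	GLU	OE1	O2'	2.8	hydrogen_bond	FALSE
syn-cAMP	185	ALA	N	O1P	2.9	hydrogen_bond	FALSE
syn-cAMP	192	ARG	NH1	NH1	2.8	hydrogen_bond	TRUE
syn-cAMP	193	THR	N	O2P	2.8	hydrogen_bond	FALSE
syn-cAMP	193	THR	OG1	O2P	2.9	hydrogen_bond	FALSE
syn-cAMP	165	VAL	CG1	C5	3.8	vdw	FALSE
syn-cAMP	165	VAL	CG1	C8	3.9	vdw	FALSE
syn-cAMP	165	VAL	CG1	N7	3.9	vdw	FALSE
syn-cAMP	172	LEU	CD(min)	N6	3.9	vdw	FALSE
syn-cAMP	172	LEU	CD(min)	C6	3.7	vdw	FALSE
syn-cAMP	173	CYS	SG	N7	3.6	vdw	FALSE
syn-cAMP	175	MET	CE	C8	3.7	vdw	FALSE
anti-cAMP	182	GLY	N	O2'	2.9	hydrogen_bond	FALSE
anti-cAMP	183	GLU	OE1	O2'	2.7	hydrogen_bond	FALSE
anti-cAMP	185	ALA	N	O1P	2.9	hydrogen_bond	FALSE
anti-cAMP	192	ARG	NH1	O1P	2.9	hydrogen_bond	FALSE
anti-cAMP	193	THR	N	O2P	2.8	hydrogen_bond	FALSE
anti-cAMP	193	THR	OG1	O2P	2.9	hydrogen_bond	FALSE
anti-cAMP	165	VAL	CG1	C4	3.9	vdw	FALSE
anti-cAMP	172	LEU	CD(min)	N6	3.6	vdw	FALSE
anti-cAMP	173	CYS	SG	C2	3.4	vdw	FALSE
apo-cAMP	182	GLY	N	O2'	2.9	hydrogen_bond	FALSE
apo-cAMP	183	GLU	OE1	O2'	2.7	hydrogen_bond	FALSE
apo-cAMP	185	ALA	N	O1P	2.9	hydrogen_bond	FALSE
apo-cAMP	192	ARG	NH1	O1P	2.9	hydrogen_bond	FALSE
apo-cAMP	193	THR	N	O2P	2.8	hydrogen_bond	FALSE
apo-cAMP	193	THR	OG1	O2P	2.9	hydrogen_bond	FALSE
apo-cAMP	173	CYS	SG	C2	3.4	vdw	FALSE
PO4	192	ARG	NH1	O4	2.8	hydrogen_bond	FALSE
PO4	193	THR	N	O1	2.7	hydrogen_bond	FALSE
PO4	193	THR	OG1	O1	2.5	hydrogen_bond	FALSE
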