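resid	elety	class_id	charge
ALA	N	6	-0.16
ALA	CA	2	0.16
ALA	C	1	0.51
ALA	O	8	-0.51
ARG	N	6	-0.16
ARG	CA	2	0.16
ARG	C	1	0.51
ARG	O	8	-0.51
ASN	N	6	-0.16
ASN	CA	2	0.16
ASN	C	1	0.51
ASN	O	8	-0.51
ASP	N	6	-0.16
ASP	CA	2	0.16
ASP	C	1	0.51
ASP	O	8	-0.51
CYS	N	6	-0.16
CYS	CA	2	0.16
CYS	C	1	0.51
CYS	O	8	-0.51
GLN	N	6	-0.16
GLN	CA	2	0.16
GLN	C	1	0.51
GLN	O	8	-0.51
GLU	N	6	-0.16
GLU	CA	2	0.16
GLU	C	1	0.51
GLU	O	8	-0.51
GLY	N	6	-0.16
GLY	CA	3	0.16
GLY	C	1	0.51
GLY	O	8	-0.51
HIS	N	6	-0.16
HIS	CA	2	0.16
HIS	C	1	0.51
HIS	O	8	-0.51
ILE	N	6	-0.16
ILE	CA	2	0.16
ILE	C	1	0.51
ILE	O	8	-0.51
LEU	N	6	-0.16
LEU	CA	2	0.16
LEU	C	1	0.51
LEU	O	8	-0.51
LYS	N	6	-0.16
LYS	CA	2	0.16
LYS	C	1	0.51
LYS	O	8	-0.51
MET	N	6	-0.16
MET	CA	2	0.16
MET	C	1	0.51
MET	O	8	-0.51
PHE	N	6	-0.16
PHE	CA	2	0.16
PHE	C	1	0.51
PHE	O	8	-0.51
PRO	N	12	-0.16
PRO	CA	2	0.16
PRO	C	1	0.51
PRO	O	8	-0.51
SER	N	6	-0.16
SER	CA	2	0.16
SER	C	1	0.51
SER	O	8	-0.51
THR	N	6	-0.16
THR	CA	2	0.16
THR	C	1	0.51
THR	O	8	-0.51
TRP	N	6	-0.16
TRP	CA	2	0.16
TRP	C	1	0.51
TRP	O	8	-0.51
TYR	N	6	-0.16
TYR	CA	2	0.16
TYR	C	1	0.51
TYR	O	8	-0.51
VAL	N	6	-0.16
VAL	CA	2	0.16
VAL	C	1	0.51
VAL	O	8	-0.51
ALA	CB	4	0
ARG	CB	3	0
ARG	CG	3	0
ARG	CD	3	0.38
ARG	NE	7	-0.26
ARG	CZ	1	0.64
ARG	NH1	7	0.12
ARG	NH2	7	0.12
ASN	CB	3	0
ASN	CG	1	0.55
ASN	OD1	8	-0.55
ASN	ND2	6	0
ASP	CB	3	-0.1
ASP	CG	1	0.62
ASP	OD1	10	-0.76
ASP	OD2	10	-0.76
CYS	CB	3	0.07
CYS	SG	11	-0.07
GLN	CB	3	0
GLN	CG	3	0
GLN	CD	1	0.55
GLN	OE1	8	-0.55
GLN	NE2	6	0
GLU	CB	3	0
GLU	CG	3	-0.1
GLU	CD	1	0.62
GLU	OE1	10	-0.76
GLU	OE2	10	-0.76
HIS	CB	3	0
HIS	CG	5	-0.05
HIS	ND1	6	-0.04
HIS	CD2	5	0.31
HIS	CE1	5	0.38
HIS	NE2	6	-0.6
ILE	CB	2	0
ILE	CG1	3	0
ILE	CG2	4	0
ILE	CD1	4	0
LEU	CB	3	0
LEU	CG	2	0
LEU	CD1	4	0
LEU	CD2	4	0
LYS	CB	3	0
LYS	CG	3	0
LYS	CD	3	0
LYS	CE	3	0.31
LYS	NZ	7	0.69
MET	CB	3	0
MET	CG	3	0.04
MET	SD	11	-0.09
MET	CE	4	0.05
PHE	CB	3	0
PHE	CG	5	0
PHE	CD1	5	0
PHE	CD2	5	0
PHE	CE1	5	0
PHE	CE2	5	0
PHE	CZ	5	0
PRO	CB	3	0
PRO	CG	3	0
PRO	CD	3	0.16
SER	CB	3	0.23
SER	OG	9	-0.23
THR	CB	2	0.25
THR	OG1	9	-0.25
THR	CG2	4	0
TRP	CB	3	0
TRP	CG	5	-0.03
TRP	CD1	5	0.06
TRP	CD2	5	0
TRP	NE1	6	-0.23
TRP	CE2	5	0.2
TRP	CE3	5	0
TRP	CZ2	5	0
TRP	CZ3	5	0
TRP	CH2	5	0
TYR	CB	3	0
TYR	CG	5	0
TYR	CD1	5	0
TYR	CD2	5	0
TYR	CE1	5	0
TYR	CE2	5	0
TYR	CZ	5	0.11
TYR	OH	9	-0.11
VAL	CB	2	0
VAL	CG1	4	0
VAL	CG2	4	0
ACE	CH3	4	0
ACE	C	1	0.51
ACE	O	8	-0.51
NME	N	6	-0.16
NME	CH3	4	0.16
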