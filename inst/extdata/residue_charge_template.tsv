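resname	atom_name	q
GLY	N	-0.41
GLY	CA	0.03
GLY	C	0.51
GLY	O	-0.51
ALA	N	-0.41
ALA	CA	0.05
ALA	C	0.51
ALA	O	-0.51
ALA	CB	-0.18
SER	N	-0.41
SER	CA	0.05
SER	C	0.51
SER	O	-0.51
SER	CB	0.05
SER	OG	-0.55
CYS	N	-0.41
CYS	CA	0.05
CYS	C	0.51
CYS	O	-0.51
CYS	CB	-0.10
CYS	SG	-0.20
ASP	N	-0.41
ASP	CA	0.05
ASP	C	0.51
ASP	O	-0.51
ASP	CB	-0.15
ASP	CG	0.60
ASP	OD1	-0.70
ASP	OD2	-0.70
LYS	N	-0.41
LYS	CA	0.05
LYS	C	0.51
LYS	O	-0.51
LYS	CB	-0.10
LYS	CG	-0.10
LYS	CD	-0.10
LYS	CE	0.10
LYS	NZ	-0.30
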