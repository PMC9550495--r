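residue	atom	h	l
ASP	OD1	0.80	0.00
ASP	OD2	0.80	0.00
GLU	OE1	0.80	0.00
GLU	OE2	0.80	0.00
LYS	NZ	0.70	0.00
ARG	NE	0.55	0.00
ARG	NH1	0.60	0.00
ARG	NH2	0.60	0.00
SER	OG	0.55	0.00
THR	OG1	0.55	0.00
TYR	OH	0.50	0.00
ASN	OD1	0.60	0.00
ASN	ND2	0.45	0.00
GLN	OE1	0.60	0.00
GLN	NE2	0.45	0.00
HIS	ND1	0.50	0.00
HIS	NE2	0.50	0.00
TRP	NE1	0.35	0.00
CYS	SG	0.20	0.30
MET	SD	0.15	0.40
*	N	0.30	0.00
*	O	0.45	0.00
*	OXT	0.60	0.00
*	C	0.10	0.60
*	CA	0.08	0.70
*	CB	0.05	0.90
*	ELEM:O	0.45	0.00
*	ELEM:N	0.30	0.00
*	ELEM:S	0.15	0.35
*	ELEM:C	0.05	1.00
*	ELEM:H	0.00	0.00
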