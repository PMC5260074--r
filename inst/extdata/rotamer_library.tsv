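resname	chi1	chi2	chi3	chi4	frequency
ALA	NA	NA	NA	NA	1.00
GLY	NA	NA	NA	NA	1.00
SER	62	NA	NA	NA	0.48
SER	-65	NA	NA	NA	0.29
SER	-177	NA	NA	NA	0.22
CYS	-65	NA	NA	NA	0.50
CYS	-177	NA	NA	NA	0.26
CYS	62	NA	NA	NA	0.23
THR	62	NA	NA	NA	0.49
THR	-65	NA	NA	NA	0.43
THR	-177	NA	NA	NA	0.07
VAL	175	NA	NA	NA	0.73
VAL	-60	NA	NA	NA	0.20
VAL	64	NA	NA	NA	0.06
LEU	-65	175	NA	NA	0.59
LEU	-177	65	NA	NA	0.29
LEU	-85	65	NA	NA	0.08
ILE	-65	170	NA	NA	0.60
ILE	-57	-60	NA	NA	0.15
ILE	62	170	NA	NA	0.10
MET	-65	-65	-70	NA	0.20
MET	-65	180	75	NA	0.15
MET	-177	180	180	NA	0.10
MET	-65	180	180	NA	0.10
ASP	-70	-15	NA	NA	0.51
ASP	-177	0	NA	NA	0.21
ASP	62	0	NA	NA	0.16
ASN	-65	-20	NA	NA	0.40
ASN	-177	-65	NA	NA	0.20
ASN	62	-75	NA	NA	0.15
GLU	-67	-178	-2	NA	0.30
GLU	-65	-65	-40	NA	0.25
GLU	-177	180	0	NA	0.20
GLN	-67	180	0	NA	0.25
GLN	-65	-65	-40	NA	0.20
GLN	-177	65	0	NA	0.10
LYS	-67	180	180	180	0.27
LYS	-177	180	180	180	0.20
LYS	-65	-68	180	180	0.10
LYS	-90	180	180	180	0.08
ARG	-67	180	180	180	0.22
ARG	-177	180	180	180	0.14
ARG	-65	-65	-65	180	0.10
ARG	-67	180	-65	-85	0.08
HIS	-65	-70	NA	NA	0.30
HIS	-177	65	NA	NA	0.20
HIS	62	-85	NA	NA	0.13
PHE	-65	90	NA	NA	0.44
PHE	-177	80	NA	NA	0.33
PHE	62	90	NA	NA	0.13
TYR	-65	90	NA	NA	0.43
TYR	-177	80	NA	NA	0.34
TYR	62	90	NA	NA	0.13
TRP	-65	95	NA	NA	0.32
TRP	-177	-105	NA	NA	0.19
TRP	62	90	NA	NA	0.14
PRO	25	-40	NA	NA	0.50
PRO	-25	40	NA	NA	0.45
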