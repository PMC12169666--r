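# C12 repulsive-slot selection matrix.  For a pair (row type i, column type j
# in {OP, OO, OQ, NQ}) the cross C12(i,j) is the product of sqrt_c12 slot
# `i_*` of type i and slot `j_*` of type j.  Both halves of the published
# matrix are preserved verbatim: i_* columns are the "selection of C12(i,i)"
# half, j_* columns the "selection of C12(j,j)" half.
# Example fixed by the source table's footnote: OP-OQ combines OP slot 2 with
# OQ slot 3.
row	i_OP	i_OO	i_OQ	i_NQ	j_OP	j_OO	j_OQ	j_NQ
O	2	1	1	2	2	1	1	2
OM	2	1	1	2	2	1	1	2
OA	2	1	2	2	2	1	2	2
OE	2	1	1	2	2	1	1	2
OW	2	1	2	2	2	1	2	2
N	2	1	2	2	2	1	2	2
NT	2	1	2	2	2	1	2	2
NL	2	1	2	2	2	1	2	2
NR	2	1	2	2	2	1	2	2
NZ	2	1	2	2	2	1	2	2
NE	2	1	2	2	2	1	2	2
C	1	1	1	1	1	1	1	1
CH0	1	1	1	1	1	1	1	1
CH1	1	1	1	1	1	1	1	1
CH2	1	1	1	1	1	1	1	1
CH3	1	1	1	1	1	1	1	1
CH4	1	1	1	1	1	1	1	1
CH2r	1	1	1	1	1	1	1	1
CR1	1	1	1	1	1	1	1	1
HC	1	1	1	1	1	1	1	1
H	1	1	1	1	1	1	1	1
DUM	1	1	1	1	1	1	1	1
S	1	1	1	1	1	1	1	1
CU1+	2	1	2	2	2	1	2	2
CU2+	2	1	2	2	2	1	2	2
FE	2	1	2	2	2	1	2	2
ZN2+	2	1	2	2	2	1	2	2
MG2+	2	1	2	2	2	1	2	2
CA2+	2	1	2	2	2	1	2	2
P	1	1	1	1	2	1	2	2
AR	1	1	1	1	1	1	1	1
F	2	1	1	2	2	1	1	2
CL	1	1	1	1	2	1	1	2
BR	1	1	1	1	2	1	1	2
CMet	1	1	1	1	1	1	1	1
OMet	2	1	2	2	2	1	2	2
NA+	2	1	2	2	2	1	2	2
CL-	2	1	1	2	2	1	1	2
CChl	1	1	1	1	1	1	1	1
CLChl	1	1	1	1	1	1	1	1
HChl	1	1	1	1	1	1	1	1
SDmso	1	1	1	1	1	1	1	1
CDmso	1	1	1	1	1	1	1	1
ODmso	2	1	1	2	2	1	1	2
CCl4	1	1	1	1	1	1	1	1
CLCl4	1	1	1	1	1	1	1	1
FTfe	2	1	1	2	2	1	1	2
CTfe	1	1	1	1	1	1	1	1
CHTfe	1	1	1	1	1	1	1	1
OTfe	2	1	1	2	2	1	1	2
CUrea	1	1	1	1	1	1	1	1
OUrea	2	1	1	2	2	1	1	2
NUrea	2	1	2	2	2	1	2	2
SI	1	1	1	1	2	1	2	2
OML	2	1	1	2	2	1	1	2
CH3L	1	1	1	1	1	1	1	1
OP	2	1	2	2	2	1	3	2
OO	1	1	1	1	1	1	1	1
OQ	3	1	1	2	2	1	1	2
NQ	2	1	2	2	2	1	2	2
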