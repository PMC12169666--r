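# Provenance metadata: initial atom-centered partial charges from electronic
# structure calculations (B3LYP, CHelpG), used as starting points for the
# empirical charge optimization.  Two values separated by "/" are
# conformer-specific (cis-cis/trans-perp for HOONO; cis/trans for HNO2 and
# ONOO-).  Never used in energy evaluation.
species	atom_role	charge	basis_set
HO2	O	-0.143	6-31G(d)
HO2	O(H)	-0.247	6-31G(d)
HO2	H	0.390	6-31G(d)
O3	O	-0.117	6-31G(d)
O3	O (central)	0.234	6-31G(d)
NO	O	0.012	6-31G(d)
NO	N	-0.012	6-31G(d)
HOONO	O	-0.141/-0.082	6-31G(d)
HOONO	N	0.071/0.102	6-31G(d)
HOONO	O (central)	0.004/-0.029	6-31G(d)
HOONO	O(H)	-0.335/-0.381	6-31G(d)
HOONO	H	0.401/0.390	6-31G(d)
HNO3	O	-0.317/-0.392	6-311++G(3df,3pd)
HNO3	N	0.768	6-311++G(3df,3pd)
HNO3	O(H)	-0.455	6-311++G(3df,3pd)
HNO3	H	0.396	6-311++G(3df,3pd)
HNO2	O	-0.151/-0.067	6-311++G(3df,3pd)
HNO2	N	0.126/0.041	6-311++G(3df,3pd)
HNO2	O(H)	-0.362/-0.304	6-311++G(3df,3pd)
HNO2	H	0.387/0.330	6-311++G(3df,3pd)
NO3-	N	1.067	6-311++G(3df,3pd)
NO3-	O	-0.689	6-311++G(3df,3pd)
NO2-	N	-0.112	6-311++G(3df,3pd)
NO2-	O	-0.444	6-311++G(3df,3pd)
ONOO-	O(N)	-0.249/-0.420	6-311++G(3df,3pd)
ONOO-	N	-0.156/0.027	6-311++G(3df,3pd)
ONOO-	O (central)	-0.046/0.072	6-311++G(3df,3pd)
ONOO-	O	-0.549/-0.679	6-311++G(3df,3pd)
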