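# Standard GROMOS 53A6 nonbonded constants for the partner atom types listed in
# the C12 selection matrix (transcription of the published 53A6 set; OML/CH3L
# are the phospholipid extension types).  Of these, only O, OM, NR, OW and H
# are engaged by the bundled RONS species themselves, and only OM's 1-4 entry
# and H's LJ-null status enter any intramolecular energy.
# Units as in atomtypes_rons.tsv.  Polar H and DUM are LJ-null by definition.
name	mass	sqrt_c6	sqrt_c12_1	sqrt_c12_2	sqrt_c12_3	sqrt_c6_14	sqrt_c12_14	description
O	15.999	0.04756	1.000e-3	1.130e-3	NA	0.04756	1.000e-3	carbonyl oxygen
OM	15.999	0.04756	0.8611e-3	1.841e-3	3.068e-3	0.04756	0.8611e-3	carboxylate / anionic oxygen
OA	15.999	0.04756	1.100e-3	1.227e-3	NA	0.04756	1.100e-3	hydroxyl oxygen
OE	15.999	0.04756	1.100e-3	1.227e-3	NA	0.04756	1.100e-3	ether / ester oxygen
OW	15.999	0.05116	1.623e-3	1.623e-3	NA	0.05116	1.623e-3	water oxygen (SPC)
N	14.007	0.04936	1.523e-3	1.943e-3	NA	0.04936	1.523e-3	peptide nitrogen
NT	14.007	0.04936	1.523e-3	2.250e-3	NA	0.04936	1.523e-3	terminal amine nitrogen
NL	14.007	0.04936	1.523e-3	2.128e-3	NA	0.04936	1.523e-3	ammonium nitrogen
NR	14.007	0.04936	1.523e-3	1.841e-3	NA	0.04936	1.523e-3	aromatic / planar-fragment nitrogen
NZ	14.007	0.04936	1.523e-3	2.148e-3	NA	0.04936	1.523e-3	arginine NH nitrogen
NE	14.007	0.04936	1.523e-3	1.984e-3	NA	0.04936	1.523e-3	arginine NE nitrogen
C	12.011	0.04838	2.222e-3	NA	NA	0.04838	2.222e-3	bare carbon
CH0	12.011	0.04838	8.278e-3	NA	NA	0.04838	2.222e-3	quaternary united carbon
CH1	13.019	0.07790	9.850e-3	NA	NA	0.05396	1.933e-3	CH united atom
CH2	14.027	0.08642	5.828e-3	NA	NA	0.06873	2.1775e-3	CH2 united atom
CH3	15.035	0.09805	5.162e-3	NA	NA	0.08278	2.456e-3	CH3 united atom
CH4	16.043	0.11480	5.760e-3	NA	NA	0.11480	5.760e-3	methane
CH2r	14.027	0.08564	5.297e-3	NA	NA	0.06873	2.1775e-3	cyclic CH2 united atom
CR1	13.019	0.07425	3.888e-3	NA	NA	0.07435	2.886e-3	aromatic CH united atom
HC	1.008	0.00920	0.123e-3	NA	NA	0.00920	0.123e-3	carbon-bound hydrogen
H	1.008	0	0	NA	NA	0	0	polar hydrogen (LJ-null)
DUM	0.001	0	0	NA	NA	0	0	dummy site (LJ-null)
S	32.06	0.09992	3.616e-3	NA	NA	0.09992	3.616e-3	sulfur
CU1+	63.546	0.02045	0.07159e-3	0.2250e-3	NA	0.02045	0.07159e-3	copper(I) ion
CU2+	63.546	0.02045	0.07159e-3	0.4091e-3	NA	0.02045	0.07159e-3	copper(II) ion
FE	55.847	0.01840	0.03200e-3	0.03200e-3	NA	0.01840	0.03200e-3	heme iron
ZN2+	65.37	0.02045	0.09716e-3	0.09716e-3	NA	0.02045	0.09716e-3	zinc ion
MG2+	24.305	0.00808	0.05838e-3	0.05838e-3	NA	0.00808	0.05838e-3	magnesium ion
CA2+	40.08	0.03170	0.7057e-3	0.7057e-3	NA	0.03170	0.7057e-3	calcium ion
P	30.974	0.12140	4.711e-3	4.711e-3	NA	0.12140	4.711e-3	phosphorus
AR	39.948	0.07915	3.138e-3	NA	NA	0.07915	3.138e-3	argon
F	18.998	0.03432	0.8722e-3	1.000e-3	NA	0.03432	0.8722e-3	covalent fluorine
CL	35.453	0.09362	3.911e-3	NA	NA	0.09362	3.911e-3	covalent chlorine
BR	79.904	0.16050	8.092e-3	NA	NA	0.16050	8.092e-3	covalent bromine
CMet	15.035	0.09421	4.400e-3	NA	NA	0.09421	4.400e-3	methanol CH3
OMet	15.999	0.04756	1.100e-3	1.227e-3	NA	0.04756	1.100e-3	methanol oxygen
NA+	22.990	0.008489	0.1450e-3	0.1450e-3	NA	0.008489	0.1450e-3	sodium ion
CL-	35.453	0.11750	10.340e-3	10.340e-3	NA	0.11750	10.340e-3	chloride ion
CChl	13.019	0.051292	2.0160e-3	NA	NA	0.051292	2.0160e-3	chloroform carbon
CLChl	35.453	0.091141	3.7101e-3	NA	NA	0.091141	3.7101e-3	chloroform chlorine
HChl	1.008	0.008158	0.0974e-3	NA	NA	0.008158	0.0974e-3	chloroform hydrogen
SDmso	32.06	0.10277	4.6366e-3	NA	NA	0.10277	4.6366e-3	DMSO sulfur
CDmso	15.035	0.09421	4.4000e-3	NA	NA	0.09421	4.4000e-3	DMSO CH3
ODmso	15.999	0.04756	0.8611e-3	1.125e-3	NA	0.04756	0.8611e-3	DMSO oxygen
CCl4	12.011	0.051292	2.7568e-3	NA	NA	0.051292	2.7568e-3	carbon tetrachloride carbon
CLCl4	35.453	0.087201	3.5732e-3	NA	NA	0.087201	3.5732e-3	carbon tetrachloride chlorine
FTfe	18.998	0.03432	0.8722e-3	1.000e-3	NA	0.03432	0.8722e-3	trifluoroethanol fluorine
CTfe	12.011	0.04838	2.222e-3	NA	NA	0.04838	2.222e-3	trifluoroethanol carbon
CHTfe	14.027	0.08642	5.828e-3	NA	NA	0.06873	2.1775e-3	trifluoroethanol CH2
OTfe	15.999	0.04756	1.100e-3	1.227e-3	NA	0.04756	1.100e-3	trifluoroethanol oxygen
CUrea	12.011	0.04838	2.2220e-3	NA	NA	0.04838	2.2220e-3	urea carbon
OUrea	15.999	0.04756	1.000e-3	1.130e-3	NA	0.04756	1.000e-3	urea oxygen
NUrea	14.007	0.04936	1.523e-3	1.943e-3	NA	0.04936	1.523e-3	urea nitrogen
SI	28.08	0.12140	4.711e-3	4.711e-3	NA	0.12140	4.711e-3	silicon
OML	15.999	0.04756	1.000e-3	1.130e-3	NA	0.04756	1.000e-3	lipid ester oxygen (phospholipid extension)
CH3L	15.035	0.09805	5.162e-3	NA	NA	0.08278	2.456e-3	lipid choline CH3 (phospholipid extension)
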