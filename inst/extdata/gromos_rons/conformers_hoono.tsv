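# Start internals for the eight HOONO conformers (angles and dihedrals in
# degrees; bonds are rigid at their b0).  Starts are the ab initio reference
# internals.  pin_onoo / pin_nooh mark dihedrals held fixed during the
# minimization: cis-gauche is not a stationary point of the classical surface
# and is restrained at its quantum-reference dihedrals; perp-perp is restrained
# at the classical stationary region of the O-N-O-O barrier (the quantum
# geometry sits on the barrier's downhill flank).  All other conformers are
# minimized freely (the all-planar ones are stationary by symmetry).
label	ONO	NOO	OOH	ONOO	NOOH	pin_onoo	pin_nooh
cis-cis	114.3	113.6	100.6	0.0	0.0	FALSE	FALSE
cis-gauche	114.0	111.9	102.0	-7.5	53.9	TRUE	TRUE
cis-perp	113.9	109.7	101.0	-5.1	92.0	FALSE	FALSE
cis-trans	114.8	108.5	95.6	0.0	180.0	FALSE	FALSE
perp-perp	109.5	96.4	99.7	95.0	100.5	TRUE	TRUE
trans-cis	110.3	106.1	100.8	180.0	0.0	FALSE	FALSE
trans-perp	108.4	104.7	100.1	176.6	101.0	FALSE	FALSE
trans-trans	108.5	102.3	96.8	180.0	180.0	FALSE	FALSE
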