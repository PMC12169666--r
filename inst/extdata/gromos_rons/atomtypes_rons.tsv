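# Nonbonded self-interaction constants of the four RONS-specific atom types.
# sqrt_c6 in (kJ mol^-1 nm^6)^1/2; sqrt_c12_* in (kJ mol^-1 nm^12)^1/2 (up to
# three repulsive slots, selected per pair via the C12 selection matrix).
# sqrt_c6_14 / sqrt_c12_14 are the modified third-neighbor (1-4) constants.
name	mass	sqrt_c6	sqrt_c12_1	sqrt_c12_2	sqrt_c12_3	sqrt_c6_14	sqrt_c12_14	description
OP	15.999	0.04756	1.334e-3	1.334e-3	NA	0.04756	1.334e-3	OH-group oxygen in hydrogen peroxide, oxyradicals and nitrogen oxyacids
OO	15.999	0.018963	0.33329e-3	NA	NA	0.018963	0.33329e-3	oxygen in molecular oxygen and nitric oxide
OQ	15.999	0.035765	1.000e-3	0.834e-3	1.784e-3	0.035765	0.834e-3	oxygen in ozone, nitrogen oxides and nitrogen oxyacids
NQ	14.007	0.035765	1.000e-3	0.834e-3	NA	0.035765	1.000e-3	nitrogen in nitrogen oxides and nitrogen oxyacids
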