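# GROMOS 54A7 emission variant: differences relative to the 53A6 tables.
# `rename` rows map 53A6-era lipid-extension type names to their 54A7 names;
# `atomtype` rows replace the ion self-interaction constants updated in 54A7.
# Transcription-grade values; they affect emitted topology text only.
kind	name	new_name	sqrt_c6	sqrt_c12_1	sqrt_c12_2	sqrt_c12_3	sqrt_c6_14	sqrt_c12_14
rename	OML	OEL	NA	NA	NA	NA	NA	NA
rename	CH3L	CH3p	NA	NA	NA	NA	NA	NA
atomtype	NA+	NA	0.008489	0.5010e-3	0.5010e-3	NA	0.008489	0.5010e-3
atomtype	CL-	NA	0.11180	8.7000e-3	8.7000e-3	NA	0.11180	8.7000e-3
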