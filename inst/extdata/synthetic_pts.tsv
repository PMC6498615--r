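system_id	substrate	component
pts_cel	cellobiose	F0031
pts_cel	cellobiose	F0032
pts_cel	cellobiose	F0033
pts_cel	cellobiose	F0034
pts_fru	fructose	F0035
pts_fru	fructose	F0036
pts_fru	fructose	F0037
pts_asc	ascorbate	F0038
pts_asc	ascorbate	F0039
pts_man	mannose	F0040
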