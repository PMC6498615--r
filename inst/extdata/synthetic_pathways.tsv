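pathway_id	name	role
aa_asp	aspartate biosynthesis (synthetic)	F0001
aa_asp	aspartate biosynthesis (synthetic)	F0002
aa_asp	aspartate biosynthesis (synthetic)	F0003
aa_asp	aspartate biosynthesis (synthetic)	F0004
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0005
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0006
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0007
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0008
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0009
aa_bcaa	branched-chain amino acid biosynthesis (synthetic)	F0010
aa_arg	arginine biosynthesis (synthetic)	F0011
aa_arg	arginine biosynthesis (synthetic)	F0012
aa_arg	arginine biosynthesis (synthetic)	F0013
aa_arg	arginine biosynthesis (synthetic)	F0014
aa_arg	arginine biosynthesis (synthetic)	F0015
aa_arg	arginine biosynthesis (synthetic)	F0016
aa_his	histidine biosynthesis (synthetic)	F0017
aa_his	histidine biosynthesis (synthetic)	F0018
aa_his	histidine biosynthesis (synthetic)	F0019
aa_his	histidine biosynthesis (synthetic)	F0020
aa_his	histidine biosynthesis (synthetic)	F0021
aa_his	histidine biosynthesis (synthetic)	F0022
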