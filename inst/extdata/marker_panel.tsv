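compound	kegg_id	formula	adduct	polarity	printed_mz
ATP	C00002	C10H16N5O13P3	M-H	negative	505.988
Heme (Fe II)	C00032	C34H32FeN4O4	M-H	negative	615.17
IMP	C00130	C10H13N4O8P	M+Na	positive	371.037
Heme (Fe III)	C00032	C34H32FeN4O4	M	positive	616.177
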