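kegg_id	hmdb_id	name	formula	monoisotopic_mass	endogenous_or_essential
C00705		2-Deoxycytidine diphosphate (dCDP)	C9H15N3O10P2	387.023267	TRUE
C00068		Thiamine diphosphate	C12H18N4O7P2S	424.037143	TRUE
C12270		N-Acetylaspartylglutamic acid	C11H16N2O8	304.090665	TRUE
C13828		Cervonoyl ethanolamide	C24H37NO2	371.282429	TRUE
C06197		Diadenosine triphosphate	C20H27N10O16P3	756.081935	TRUE
C00206		2-Deoxyadenosine 5-diphosphate	C10H15N5O9P2	411.0345	TRUE
C16511		l-Homocysteic acid	C4H9NO5S	183.020143	TRUE
C03287		l-Glutamic acid 5-phosphate	C5H10NO7P	227.019488	TRUE
C06232		Molybdate	H2MoO4	163.900717	TRUE
C01060		3,5-Diiodo-l-tyrosine	C9H9I2NO3	432.867189	TRUE
C00131		2-Deoxyadenosine 5-triphosphate (dATP)	C10H16N5O12P3	491.000831	TRUE
C00513		CDP-glycerol	C12H21N3O13P2	477.054961	TRUE
C01345		2-Deoxyinosine triphosphate	C10H15N4O13P3	491.984846	TRUE
C05704		Selenocystine	C6H12N2O4Se2	335.912749	TRUE
C06125		3-O-Sulfogalactosylceramide (d18:1/14:0)	C38H73NO11S	751.490433	TRUE
C03451		S-Lactoylglutathione	C13H21N3O8S	379.104936	TRUE
C00440		5-Methyltetrahydrofolic acid	C20H25N7O6	459.186632	TRUE
C00032		Heme	C34H32FeN4O4	616.177293	TRUE
C04426		Uridine diphosphate acetylgalactosamine 4-sulfate	C17H27N3O20P2S	687.038385	TRUE
C00024		Acetyl-CoA	C23H38N7O17P3S	809.125774	TRUE
C00798		Formyl-CoA	C22H36N7O17P3S	795.110124	TRUE
C11499		(S)-3-Sulfonatolactate	C3H6O6S	169.988509	TRUE
C02470		Xanthurenic acid	C10H7NO4	205.037508	TRUE
C00836		Sphinganine	C18H39NO2	301.298079	TRUE
C00104		Inosine 5-diphosphate (IDP)	C10H14N4O11P2	428.013431	TRUE
C06054		2-Oxo-3-hydroxy-4-phosphobutanoic acid	C4H7O8P	213.987854	TRUE
C00081		Inosine triphosphate (ITP)	C10H15N4O14P3	507.979761	TRUE
C03204		10-Formyldihydrofolate	C20H21N7O7	471.150246	TRUE
C00006		NADP	C21H28N7O17P3	743.075452	TRUE
C02739		Phosphoribosyl-ATP	C15H25N5O20P4	719.004335	TRUE
C01190		GlcCer(d18:1/25:0)	C49H95NO8	825.705769	TRUE
C05527		3-Sulfinylpyruvic acid	C3H4O5S	151.977944	TRUE
C05688		l-Selenocysteine	C3H7NO2Se	168.9642	TRUE
C05925		Dihydroneopterin phosphate	C9H14N5O7P	335.063084	TRUE
C00119		Phosphoribosyl pyrophosphate	C5H13O14P3	389.951815	TRUE
C00445		(6R)-5,10-Methenyltetrahydrofolate	C20H21N7O6	455.155331	TRUE
C19851		ADP-ribose 1-2 cyclic phosphate	C15H22N5O16P3	621.02744	TRUE
C04856		NADHX	C21H31N7O15P2	683.135337	TRUE
C00005		NADPH	C21H30N7O17P3	745.091102	TRUE
C05692		Se-Adenosyl-l-selenohomocysteine	C14H20N6O5Se	432.066039	TRUE
C00002		Adenosine triphosphate (ATP)	C10H16N5O13P3	506.995745	TRUE
C00130		Inosine monophosphate (IMP)	C10H13N4O8P	348.0471	TRUE
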