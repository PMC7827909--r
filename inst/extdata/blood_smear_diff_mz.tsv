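mz	adduct	kegg_id	metabolite	ratio	setting	cell_type	validates
367.99194	M-H20-H	C00705	2-Deoxycytidine diphosphate (dCDP)	0.8	D0-	RBC	TRUE
423.02167	M-H	C00068	Thiamine diphosphate	>0.1	D1-	RBC	TRUE
607.17777	2M-H	C12270	N-Acetylaspartylglutamic acid	0.3	D1-	RBC	TRUE
743.53308	2M-H	C13828	Cervonoyl ethanolamide	6.5	D1-	RBC	FALSE
755.09679	M-H	C06197	Diadenosine triphosphate	>0.1	D1-	RBC	TRUE
821.05335	2M-H	C00206	2-Deoxyadenosine 5-diphosphate	>0.1	D1-	RBC	TRUE
221.97144	M+K	C16511	l-Homocysteic acid	1.6	D0+	RBC	TRUE
265.96063	M+K	C03287	l-Glutamic acid 5-phosphate	1.2	D0+	RBC	TRUE
326.77131	2M+H	C06232	Molybdate	2.0	D0+	RBC	FALSE
415.84174	M+H-H2O	C01060	3,5-Diiodo-l-tyrosine	0.8	D0+	RBC	TRUE
456.0047	M+H-2H2O	C00131	2-Deoxyadenosine 5-triphosphate (dATP)	1.4	D0+	RBC	TRUE
500.04952	M+Na	C00513	CDP-glycerol	2.8	D0+	RBC	TRUE
514.96755	M+Na	C01345	2-Deoxyinosine triphosphate	0.5	D0+	RBC	TRUE
694.83621	2M+Na	C05704	Selenocystine	0.7	D0+	RBC	TRUE
790.43199	M+K	C06125	3-O-Sulfogalactosylceramide (d18:1/14:0)	0.7	D0+	RBC	TRUE
418.04554	M+K	C03451	S-Lactoylglutathione	0.6	D1+	RBC	TRUE
498.14504	M+K	C00440	5-Methyltetrahydrofolic acid	1.2	D1+	RBC	TRUE
616.17073	M+H	C00032	Heme	1.6	D1+	RBC	FALSE
652.04788	M+H-2H2O	C04426	Uridine diphosphate acetylgalactosamine 4-sulfate	0.7	D1+	RBC	TRUE
774.11178	M+H-2H2O	C00024	Acetyl-CoA	0.6	D1+	RBC	TRUE
796.1011	M+H	C00798	Formyl-CoA	0.9	D1+	RBC	TRUE
338.96305	2M-H	C11499	(S)-3-Sulfonatolactate	0.5	D0-	WBC	TRUE
367.99194	M-H20-H	C00705	2-Deoxycytidine diphosphate (dCDP)	0.6	D0-	WBC	TRUE
409.06403	2M-H	C02470	Xanthurenic acid	1.7	D0-	WBC	TRUE
601.60302	2M-H	C00836	Sphinganine	0.6	D0-	WBC	TRUE
409.00689	M-H20-H	C00104	Inosine 5-diphosphate (IDP)	0.8	D1-	WBC	TRUE
426.95079	2M-H	C06054	2-Oxo-3-hydroxy-4-phosphobutanoic acid	17.8	D1-	WBC	TRUE
488.97877	M-H20-H	C00081	Inosine triphosphate (ITP)	3.2	D1-	WBC	TRUE
506.11841	M+Cl	C03204	10-Formyldihydrofolate	9.2	D1-	WBC	TRUE
506.99341	M-H	C00081	Inosine triphosphate (ITP)	1.9	D1-	WBC	TRUE
724.08168	M-H20-H	C00006	NADP	>0.1	D1-	WBC	TRUE
743.53308	2M-H	C13828	Cervonoyl ethanolamide	0.3	D1-	WBC	FALSE
753.97899	M+Cl	C02739	Phosphoribosyl-ATP	>0.1	D1-	WBC	TRUE
806.70364	M-H20-H	C01190	GlcCer(d18:1/25:0)	>0.1	D1-	WBC	TRUE
221.97144	M+K	C16511	l-Homocysteic acid	1.8	D0+	WBC	TRUE
265.96063	M+K	C03287	l-Glutamic acid 5-phosphate	1.5	D0+	WBC	TRUE
326.9293	2M+Na	C05527	3-Sulfinylpyruvic acid	0.5	D0+	WBC	TRUE
376.89968	2M+K	C05688	l-Selenocysteine	2.8	D0+	WBC	TRUE
415.84174	M+H-H2O	C01060	3,5-Diiodo-l-tyrosine	0.7	D0+	WBC	TRUE
456.0047	M+H-2H2O	C00131	2-Deoxyadenosine 5-triphosphate (dATP)	1.8	D0+	WBC	TRUE
694.83621	2M+Na	C05704	Selenocystine	0.6	D0+	WBC	TRUE
701.98995	M+H-H2O	C02739	Phosphoribosyl-ATP	0.6	D0+	WBC	TRUE
709.07265	2M+K	C05925	Dihydroneopterin phosphate	1.7	D0+	WBC	TRUE
762.92406	2M+H-H2O	C00119	Phosphoribosyl pyrophosphate	0.6	D0+	WBC	TRUE
478.16774	M+Na	C00445	(6R)-5,10-Methenyltetrahydrofolate	0.7	D1+	WBC	TRUE
586.02355	M+H-2H2O	C19851	ADP-ribose 1-2 cyclic phosphate	0.4	D1+	WBC	TRUE
706.13261	M+Na	C04856	NADHX	0.4	D1+	WBC	TRUE
728.10302	M+H-H2O	C00005	NADPH	0.9	D1+	WBC	TRUE
779.09063	M+Na	C06197	Diadenosine triphosphate	1.0	D1+	WBC	TRUE
865.13597	2M+H	C05692	Se-Adenosyl-l-selenohomocysteine	0.5	D1+	WBC	TRUE
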