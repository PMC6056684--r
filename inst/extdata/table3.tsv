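protein	accession	mw_kda	control	ouabain
14-3-3 protein beta/alpha	Q9CQV8	28	3	6
14-3-3 protein epsilon	P62259	29	2	3
14-3-3 protein zeta/delta	P63101	28	6	5
2',3'-cyclic-nucleotide 3'-phosphodiesterase	P16330	47	3	0
3-hydroxyacyl-CoA dehydrogenase type-2	A2AFQ2	28	2	0
40S ribosomal protein S3	P62908	27	1	2
60 kDa heat shock protein, mitochondrial	P63038	61	2	0
78 kDa glucose-regulated protein	P20029	72	3	5
Aconitate hydratase, mitochondrial	Q99KI0	85	5	1
Actin, aortic smooth muscle	P62737	42	20	19
Actin, cytoplasmic 1	P60710	42	23	19
Adenylate kinase isoenzyme 1	Q9R0Y5	22	2	1
ADP/ATP translocase 1	P48962	33	8	1
ADP-ribosylation factor 5	P84084	21	2	0
Aldehyde dehydrogenase, mitochondrial	P47738	57	2	1
Alkaline phosphatase, tissue-nonspecific isozyme	P09242	58	0	2
Alpha-1-antitrypsin 1-1	P07758	46	3	4
Alpha-2-HS-glycoprotein	P29699	37	3	1
Alpha-2-macroglobulin	Q61838	166	1	3
Alpha-actinin-1	Q7TPR4	103	6	2
Alpha-actinin-2	Q9JI91	104	6	0
Alpha-enolase	P17182	47	7	4
Androgen receptor	P19091	98	2	1
Annexin A1	P10107	39	0	2
Annexin A2	P07356	39	2	2
Annexin A5	P48036	36	5	2
Annexin A6	P14824	76	2	1
Apolipoprotein A-I	Q00623	31	2	4
Apolipoprotein E	P08226	36	5	2
Aspartate aminotransferase, cytoplasmic	P05201	46	2	0
Aspartate aminotransferase, mitochondrial	P05202	47	4	1
ATP synthase subunit alpha, mitochondrial	Q03265	60	11	1
ATP synthase subunit b, mitochondrial	Q9CQQ7	29	3	0
ATP synthase subunit beta, mitochondrial	P56480	56	11	5
ATP synthase subunit f, mitochondrial	P56135	10	2	1
Basement membrane-specific heparan sulfate proteoglycan core protein	B1B0C7	469	2	3
Beta-enolase	P21550	47	8	0
Biglycan	P28653	42	3	0
Calmodulin	P62204	17	3	0
Calponin-3	Q9DAW9	36	0	2
Calreticulin	P14211	48	2	0
Calsequestrin-1	O09165	46	4	0
Carbonic anhydrase 1	P13634	28	4	0
Carbonic anhydrase 2	P00920	29	5	0
Carbonic anhydrase 3	P16015	29	3	1
Citrate synthase, mitochondrial	Q9CZU6	52	2	1
Cleavage and polyadenylation-specificity factor subunit 6	H3BJW3	63	0	2
Cochlin	Q62507	60	59	46
Collagen alpha-1(I) chain	P11087	138	23	11
Collagen alpha-1(II) chain	P28481	142	6	2
Collagen alpha-1(V) chain	O88207	184	3	3
Collagen alpha-1(VI) chain	Q04857	108	4	0
Collagen alpha-1(XII) chain	Q60847	340	3	2
Collagen alpha-1(XIV) chain	Q80X19	193	4	0
Collagen alpha-2(I) chain	Q01149	130	11	9
Collagen alpha-2(VI) chain	Q02788	110	3	1
Collagen alpha-4(VI) chain	A2AX52	251	0	2
Complement C3	P01027	186	4	14
Creatine kinase B-type	Q04447	43	4	4
Creatine kinase M-type	P07310	43	14	0
Creatine kinase S-type, mitochondrial	Q6P8J7	47	4	0
Cytochrome b-c1 complex subunit 2, mitochondrial	Q9DB77	48	1	2
Desmoplakin	E9Q557	333	2	1
Destrin	Q9R0P5	19	0	2
Dihydropyrimidinase-related protein 3	Q62188	62	2	0
Dynamin-1	P39053	98	0	2
EH domain-binding protein 1-like protein 1	Q99MS7	185	0	2
Electron transfer flavoprotein subunit alpha, mitochondrial	Q99LC5	35	1	2
Elongation factor 1-alpha 1	P10126	50	6	3
Elongation factor 2	P58252	95	2	0
Endoplasmin	P08113	92	3	0
Eukaryotic initiation factor 4A-I	P60843	46	0	3
Fas-binding factor 1	A2A870	130	0	2
F-box only protein 2	Q80UW2	34	2	1
Ferritin light chain 1	P29391	21	4	0
Fibrinogen beta chain	Q8K0E8	55	0	4
Filamin-A	Q8BTM8	281	4	0
Fragile X mental retardation syndrome-related protein 2	Q9WVR4	74	2	0
Fructose-bisphosphate aldolase A	P05064	39	13	4
Fructose-bisphosphate aldolase C	P05063	39	0	3
Glutathione reductase, mitochondrial	P47791	54	0	2
Glyceraldehyde-3-phosphate dehydrogenase	P16858	36	10	5
Glycogen phosphorylase, brain form	Q8CI94	97	1	2
Guanine nucleotide-binding protein G(i) subunit alpha-2	P08752	40	3	0
Guanine nucleotide-binding protein G(I)/G(S)/G(T) subunit beta-2	P62880	37	3	1
HAUS augmin-like complex subunit 3	Q8QZX2	66	0	2
Heat shock cognate 71 kDa protein	P63017	71	4	4
Heat shock protein HSP 90-beta	P11499	83	4	2
Hemoglobin subunit alpha	P01942	15	27	10
Hemoglobin subunit beta-1	P02088	16	34	14
Hemoglobin subunit beta-2	P02089	16	26	10
Hemopexin	Q91X72	51	0	4
Heterogeneous nuclear ribonucleoprotein U	Q8VEK3	88	1	2
Histone H1.3	P43277	22	3	0
Histone H2A type 2-C	Q64523	14	11	7
Histone H2A.Z	P0C0S6	14	6	0
Histone H2B type 1-F/J/L	P10853	14	6	4
Histone H3.3C	P02301	15	3	3
Histone H4	P62806	11	6	2
Isocitrate dehydrogenase [NAD] subunit gamma 1, mitochondrial	P70404	43	2	0
Lactoylglutathione lyase	Q9CPU0	21	2	0
Laminin subunit alpha-2	Q60675	343	1	2
Laminin subunit gamma-1	F8VQJ3	177	1	2
L-lactate dehydrogenase A chain	P06151	36	3	1
L-lactate dehydrogenase B chain	P16125	37	2	3
Lysine-specific demethylase 6B	Q5NCY0	176	0	2
Malate dehydrogenase, mitochondrial	P08249	36	5	4
MCG13402, isoform CRA_a	Q8BGJ5	57	2	0
MCG140437, isoform CRA_d	G3UW82	223	70	0
Microtubule-associated serine/threonine-protein kinase 4	Q811L6	284	2	0
Mimecan	Q62000	34	5	0
Molybdenum cofactor biosynthesis protein 1	Q5RKZ7	70	1	2
Myelin basic protein (Fragment)	F6RT34	23	9	4
Myelin protein P0	P27573	28	4	5
Myoglobin	P04247	17	6	0
Myosin light chain 1/3, skeletal muscle isoform	P05977	21	11	1
Myosin regulatory light chain 2, skeletal muscle isoform	P97457	19	7	0
Myosin, heavy polypeptide 13, skeletal muscle	B1AR69	224	28	0
Myosin-1	Q5SX40	223	105	5
Myosin-3	P13541	224	35	0
Myosin-4	Q5SX39	223	82	0
Myosin-9	Q8VDD5	226	10	6
Neurofilament heavy polypeptide	P19246	117	5	1
Neurofilament light polypeptide	P08551	62	7	4
Neurofilament medium polypeptide	P08553	96	4	2
Nucleophosmin	Q61937	33	2	0
Parvalbumin alpha	P32848	12	5	1
Peptidyl-prolyl cis-trans isomerase A	P17742	18	2	2
Periaxin	O55103	148	14	4
Periostin	Q62009	93	3	0
Peroxiredoxin-1	P35700	22	2	0
Phosphoglycerate kinase 1	P09411	45	6	4
Phosphoglycerate mutase 2	O70250	29	3	1
Pig Trypsin Precursor	P00761	24	3	1
Plastin-2	Q61233	70	2	0
Polyubiquitin-B	P0CG49	34	2	1
Prelamin-A/C	P48678	74	0	2
Protein Ahnak	E9Q616	604	2	1
Protein Arid1b	E9Q4N6	191	0	2
Protein Col22a1	E9Q7P1	160	9	0
Protein Col6a3	E9PWQ3	354	5	1
Protein disulfide-isomerase A6	Q922R8	48	2	2
Protein Fga	E9PV24	87	0	2
Protein Iqgap3	F8VQ29	185	2	0
Protein NDRG1	Q62433	43	3	1
Protein S100-A9	P31725	13	1	5
Protein Wnt-3a	P27467	39	0	2
Prothrombin	P19221	70	2	0
Putative adenosylhomocysteinase 3	Q68FL4	67	1	2
Pyruvate dehydrogenase E1 component subunit alpha, somatic form, mitochondrial	P35486	43	2	0
Pyruvate kinase isozymes M1/M2	P52480	58	16	2
Ras GTPase-activating-like protein IQGAP1	Q9JKF1	189	2	0
Rho GDP-dissociation inhibitor 1	Q99PT1	23	2	0
RNA-binding protein 42	Q91V81	50	1	3
Ryanodine receptor 2	E9Q401	565	2	0
Sarcalumenin	Q7TQ48	99	2	0
Sarcoplasmic/endoplasmic reticulum calcium ATPase 1	Q8R429	109	27	0
Serine/threonine-protein phosphatase 2A 65 kDa regulatory subunit A alpha isoform	Q76MZ3	65	2	1
Serotransferrin	Q921I1	77	2	6
Serum albumin	P07724	69	8	5
Serum amyloid P-component	P12246	26	0	2
Sodium/potassium-transporting ATPase subunit alpha-1	Q8VDN2	113	8	8
Sodium/potassium-transporting ATPase subunit alpha-2	Q6PIE5	112	5	5
Solute carrier family 12 member 2	P55012	131	2	0
Spectrin alpha chain, non-erythrocytic 1	P16546	285	2	3
Spectrin beta chain, non-erythrocytic 1	Q62261	274	2	3
S-phase kinase-associated protein 1	Q9WTX5	19	3	0
Syntaxin-1B	P61264	33	0	2
Talin-1	P26039	270	3	2
Thrombospondin-1	P35441	130	0	5
Titin	A2ASS6	3906	5	2
TPR and ankyrin repeat-containing protein 1	Q8BV79	343	0	2
Transcription factor HIVEP2	Q3UHF7	267	0	2
Transitional endoplasmic reticulum ATPase	Q01853	89	2	4
Transketolase	P40142	68	2	1
Trifunctional enzyme subunit alpha, mitochondrial	Q8BMS1	83	2	0
Triosephosphate isomerase	P17751	32	3	2
Tubulin alpha-1A chain	P68369	50	10	9
Tubulin beta-4B chain	P68372	50	7	4
Tubulin beta-5 chain	P99024	50	8	4
Tyrosine-protein phosphatase non-receptor type 12	P35831	87	2	0
U3 small nucleolar RNA-associated protein 14 homolog B	Q6EJB6	86	1	2
Ubiquitin-like modifier-activating enzyme 1	Q02053	118	2	0
Uncharacterized protein	E9Q070	34	2	0
Uncharacterized protein	D3Z2H9	29	2	0
Vimentin	P20152	54	4	6
Vinculin	Q64727	117	0	2
Vitamin K-dependent protein Z	Q9CQW3	44	2	0
Vitronectin	P29788	55	5	3
Y-box-binding protein 2	Q9Z2C8	38	2	0
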