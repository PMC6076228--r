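##fileformat=VCFv4.2
##source=mendeldx
##comment=Nine probands with independently validated mutations; 11 records. Gene, disease and coding-level (HGVS) mutation descriptions are as published; genomic coordinates are SYNTHETIC placeholders on the correct chromosomes.
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CONSEQ,Number=1,Type=String,Description="Functional consequence">
##INFO=<ID=END,Number=1,Type=Integer,Description="End position of CNV">
##INFO=<ID=ZYG,Number=1,Type=String,Description="Zygosity">
##INFO=<ID=PROBAND,Number=1,Type=String,Description="Proband id">
##INFO=<ID=DISEASE,Number=1,Type=String,Description="Disease name">
##INFO=<ID=HGVS,Number=1,Type=String,Description="Coding-level mutation as published">
##INFO=<ID=VALID,Number=1,Type=String,Description="Orthogonal validation method">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	179520538	.	G	A	.	PASS	GENE=NPHS2;CONSEQ=missense;ZYG=het;PROBAND=P7;DISEASE=Nephrotic_Syndrome_Type_2;HGVS=c.538G>A;VALID=Sanger
1	179520593	.	A	C	.	PASS	GENE=NPHS2;CONSEQ=missense;ZYG=het;PROBAND=P7;DISEASE=Nephrotic_Syndrome_Type_2;HGVS=c.593A>C;VALID=Sanger
12	102151090	.	C	T	.	PASS	GENE=GNPTAB;CONSEQ=nonsense;ZYG=het;PROBAND=P3;DISEASE=Mucolipidosis_II/III_Alpha&Beta;HGVS=c.1090C>T;VALID=Sanger
12	102152404	.	C	T	.	PASS	GENE=GNPTAB;CONSEQ=missense;ZYG=het;PROBAND=P3;DISEASE=Mucolipidosis_II/III_Alpha&Beta;HGVS=c.2404C>T;VALID=Sanger
16	2168835	.	C	G	.	PASS	GENE=PKD1;CONSEQ=missense;ZYG=het;PROBAND=P5;DISEASE=Polycystic_kidney_disease_1;HGVS=c.8835C>G;VALID=Sanger
16	23381853	.	C	G	.	PASS	GENE=SCNN1B;CONSEQ=missense;ZYG=het;PROBAND=P8;DISEASE=Pseudohypoaldosteronism_Type_IB;HGVS=c.1853C>G;VALID=Sanger
17	15134215	.	C	T	.	PASS	GENE=PMP22;CONSEQ=missense;ZYG=het;PROBAND=P4;DISEASE=Charcot-Marie-Tooth_disease;HGVS=c.215C>T;VALID=Sanger
17	15129200	.	N	<DUP>	.	PASS	GENE=PMP22;CONSEQ=other;END=15169200;ZYG=het;PROBAND=P9;DISEASE=Charcot-Marie-Tooth_disease;HGVS=Whole_gene_duplication;VALID=QPCR
X	7137500	.	N	<DEL>	.	PASS	GENE=STS;CONSEQ=other;END=7272800;ZYG=hemi;PROBAND=P2;DISEASE=X-Linked_Ichthyosis;HGVS=Whole_gene_deletion;VALID=QPCR
X	32600000	.	N	<DEL>	.	PASS	GENE=DMD;CONSEQ=other;END=32700000;ZYG=hemi;PROBAND=P6;DISEASE=Duchenne/Becker_Muscular_Dystrophy;HGVS=CDS_10-12_deletion;VALID=QPCR
X	49850778	.	GACTCTGGTTATCAAAACCATC	G	.	PASS	GENE=CLCN5;CONSEQ=inframe_indel;ZYG=hemi;PROBAND=P1;DISEASE=Dent_Disease_1;HGVS=c.778_798delACTCTGGTTATCAAAACCATC;VALID=Sanger
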