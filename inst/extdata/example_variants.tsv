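chrom	pos	ref	alt	gene	strand	site_kind	region	class	initial_ri	final_ri	cryptic_pos	samples
chr5	162905690	G	T	HMMR	+	acceptor	exonic	natural	12.83	10.67	.	SAMPLE_A
chr10	89711873	A	G	PTEN	+	acceptor	intronic	natural	12.09	-2.62	.	SAMPLE_B
chr12	83359523	G	A	TMTC2	+	donor	exonic	natural	1.74	-1.27	.	SAMPLE_C
chr1	985377	C	T	AGRN	+	donor	exonic	cryptic	-2.24	4.79	985376	SAMPLE_D
chr1	46726876	G	T	RAD54L	+	donor	intronic	cryptic	13.4	14.84	46726895	SAMPLE_I,SAMPLE_II,SAMPLE_III,SAMPLE_IV,SAMPLE_V,SAMPLE_VI
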