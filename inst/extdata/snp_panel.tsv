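rs_id	gene	gene_alias	chromosome_position	domain	major_allele	minor_allele	category	metabolized_species	note
rs700519	CYP19A1	NA	Chr15:51507968	exon7	G	A	enzyme	E1(E2)	NA
rs1048943	CYP1A1	NA	Chr15:75012985	exon7	T	C	enzyme	2-OHE1(E2)	NA
rs4646903	CYP1A1	NA	Chr15:75011641	3'-flanking	A	G	enzyme	2-OHE1(E2)	also printed as rs4649903 in some reports
rs1056827	CYP1B1	NA	Chr2:38302177	exon2	C	A	enzyme	4-OHE1(E2)	also printed as rs10526827 in some reports
rs1056836	CYP1B1	NA	Chr2:38298203	exon3	G	C	enzyme	4-OHE1(E2)	NA
rs605059	HSD17B1	NA	Chr17:40706906	exon6	G	A	enzyme	E2	NA
rs4680	COMT	NA	Chr22:19951271	exon4	G	A	enzyme	2(4)-MeOE1(2)	NA
rs1042028	SULT1A1	NA	Chr16:28617514	exon7	C	T	enzyme	sulfated metabolites	NA
rs7439366	UGT2B7	NA	Chr4:69964338	exon2	C	T	enzyme	glucuronide metabolites	NA
rs10822013	ZNF365	NA	Chr10:64251977	intron4	C	T	gwas	NA	NA
rs2981579	FGFR2	NA	Chr10:123337335	intron2	G	A	gwas	NA	NA
rs3784099	RAD51B	NA	Chr14:68749927	intron7	G	A	gwas	NA	NA
rs3803662	TOX3	CASC16	Chr16:52586341	exon4	A	G	gwas	NA	minor allele G is the first-listed genotype in the published counts
rs889312	MAP3K1	NA	Chr5:56031884	NA	C	A	gwas	NA	NA
rs981782	HCN1	NA	Chr5:45285616	intron6	A	C	gwas	NA	allele labels printed as G/A in panel metadata but C/A in the genotype counts; C/A used here
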