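chr1	example	exon	1	100	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr1	example	exon	51	150	.	+	.	gene_id "geneA"; transcript_id "geneA.t2";
chr1	example	exon	500	799	.	+	.	gene_id "geneA"; transcript_id "geneA.t1";
chr2	example	exon	10	10	.	-	.	gene_id "geneB"; transcript_id "geneB.t1";
chr2	example	exon	1000	1999	.	-	.	gene_id "geneB"; transcript_id "geneB.t1";
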