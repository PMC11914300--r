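syn_eif5a_mirror	synthetic	exon	1	103	.	+	.	gene_id "SYN_EIF5A"; transcript_id "TX_EIF5A_MIRROR"; gene_biotype "protein_coding";
syn_eif5a_mirror	synthetic	exon	200	305	.	+	.	gene_id "SYN_EIF5A"; transcript_id "TX_EIF5A_MIRROR"; gene_biotype "protein_coding";
syn_eif5a_mirror	synthetic	CDS	11	103	.	+	.	gene_id "SYN_EIF5A"; transcript_id "TX_EIF5A_MIRROR"; gene_biotype "protein_coding";
syn_eif5a_mirror	synthetic	CDS	200	292	.	+	.	gene_id "SYN_EIF5A"; transcript_id "TX_EIF5A_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	exon	1	133	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C1_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	exon	173	308	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C1_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	CDS	11	133	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C1_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	CDS	173	295	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C1_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	exon	1	308	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C2_MIRROR"; gene_biotype "protein_coding";
syn_hnrnpc_mirror	synthetic	CDS	11	295	.	+	.	gene_id "SYN_HNRNPC"; transcript_id "TX_HNRNPC_C2_MIRROR"; gene_biotype "protein_coding";
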