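individual_id	gene	class	DP	GQ	allele_ratio	maf_cohort	maf_reference	loftee_hc	alphamissense	spliceai_delta	father_carrier	mother_carrier
ind1	geneA	missense	10	45	0.50	0.0000	0.0000	NA	0.95	NA	FALSE	FALSE
ind2	geneA	missense	30	20	0.50	0.0000	0.0000	NA	0.95	NA	FALSE	FALSE
ind3	geneB	missense	30	45	0.10	0.0000	0.0000	NA	0.95	NA	FALSE	FALSE
ind4	geneB	missense	30	45	0.50	0.0100	0.0000	NA	0.95	NA	FALSE	FALSE
ind5	geneC	missense	30	45	0.50	0.0000	0.0000	NA	0.50	NA	FALSE	FALSE
ind6	geneC	missense	30	45	0.50	0.0000	0.0000	NA	0.95	NA	FALSE	FALSE
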