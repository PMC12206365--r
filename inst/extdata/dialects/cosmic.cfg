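# COSMIC genome-variant export (GRCh38)
source = cosmic
build = GRCh38
chrom = CHROMOSOME
pos = GENOME_START
ref = GENOMIC_WT_ALLELE
alt = GENOMIC_MUT_ALLELE
protein_change = MUTATION_AA
sample_id = SAMPLE_ID
cancer_type = PRIMARY_SITE
rsid = RSID
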