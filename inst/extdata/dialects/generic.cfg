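# generic TSV dialect: canonical column names, GRCh38 unless overridden
source = generic
build = GRCh38
chrom = chrom
pos = pos
ref = ref
alt = alt
protein_change = protein_change
isoform = isoform
rsid = rsid
pathogenicity = pathogenicity
allele_frequency = allele_frequency
sample_id = sample_id
cancer_type = cancer_type
pos_hg19 = pos_hg19
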