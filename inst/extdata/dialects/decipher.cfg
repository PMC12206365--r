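# Decipher clinical-variant export (GRCh38)
source = decipher
build = GRCh38
chrom = chr
pos = start
ref = ref_allele
alt = alt_allele
pathogenicity = pathogenicity
protein_change = protein_change
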