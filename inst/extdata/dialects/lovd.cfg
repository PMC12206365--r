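# LOVD3 export; carries both builds
source = lovd
build = GRCh38
chrom = chromosome
pos = position_g38
pos_hg19 = position_g19
ref = ref
alt = alt
rsid = rsid
pathogenicity = effect
protein_change = protein
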