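# gnomAD v3-style export (GRCh38)
source = gnomad
build = GRCh38
chrom = CHROM
pos = POS
ref = REF
alt = ALT
rsid = RSID
allele_frequency = AF
protein_change = HGVSp
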