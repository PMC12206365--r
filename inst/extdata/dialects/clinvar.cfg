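# ClinVar gene-search export; carries both builds
source = clinvar
build = GRCh38
chrom = Chromosome
pos = PositionGRCh38
pos_hg19 = PositionGRCh37
ref = ReferenceAllele
alt = AlternateAllele
rsid = RSID
pathogenicity = ClinicalSignificance
protein_change = ProteinChange
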