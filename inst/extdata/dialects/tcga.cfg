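# cBioPortal MAF-style TCGA export; only hg19 positions are available
source = tcga
build = hg19
chrom = Chromosome
pos = Start_Position
ref = Reference_Allele
alt = Tumor_Seq_Allele2
protein_change = HGVSp_Short
sample_id = Tumor_Sample_Barcode
cancer_type = Study
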