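# Single-exon TREX1 gene model, GRCh38 (+ strand).
# CDS anchors derived from printed variant coordinates of the b isoform:
# codon 177 third base at chr3:48467186 and codon 266 second base at
# chr3:48467452 both give CDS start 48466656; 314 codons + stop -> 48467600.
# Isoform a adds 55 aa N-terminal (165 nt upstream); c starts 10 aa
# (30 nt) downstream of b.
chrom = chr3
gene_start = 48465519
gene_end = 48467644
flank = 2000
cds_a_start = 48466491
cds_a_end = 48467600
cds_b_start = 48466656
cds_b_end = 48467600
cds_c_start = 48466686
cds_c_end = 48467600
protein_length_a = 369
protein_length_b = 314
protein_length_c = 304
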