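chrom,length_Mbp,centromere_Mbp
chr1,248.96,123.4
chr2,242.19,93.9
chr3,198.30,90.9
chr4,190.21,50.0
chr5,181.54,48.8
chr6,170.81,59.8
chr7,159.35,60.1
chr8,145.14,45.2
chr9,138.39,43.0
chr10,133.80,39.8
chr11,135.09,53.4
chr12,133.28,35.5
chr13,114.36,17.7
chr14,107.04,17.2
chr15,101.99,19.0
chr16,90.34,36.8
chr17,83.26,25.1
chr18,80.37,18.5
chr19,58.62,26.2
chr20,64.44,28.1
chr21,46.71,12.0
chr22,50.82,15.0
chrX,156.04,61.0
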