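leaf	count
protein_coding	13539
lincRNA	509
antisense	551
sense_intronic	59
sense_overlapping	4
three_prime_overlapping	1
miRNA	116
snoRNA	81
snRNA	20
rRNA	10
miscRNA	38
processed_transcript	319
pseudogene	767
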