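sample_id	group	input_read_pairs	uniquely_mapped
N1	exposed	39371421	28694853
N2	exposed	33778273	23411127
N3	exposed	37980952	26573624
N4	exposed	43271579	31630187
N5	exposed	98021209	67023419
N6	exposed	25381274	18901075
C1	control	43903675	28076176
C2	control	31996428	22462184
C3	control	39669137	26617656
C4	control	31587579	23443335
C5	control	46728455	33418612
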