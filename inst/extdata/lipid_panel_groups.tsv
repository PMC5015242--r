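group	triglycerides	total_cholesterol	hdl_cholesterol
nicotine_std	48.1	67.5	50.6
control_std	44.6	64.7	48.9
nicotine_hfd	61.9	156.5	124.3
control_hfd	67.0	166.8	125.9
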