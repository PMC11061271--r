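chrom	pos	cm
chr2	1	0
chr2	1e+07	10.5
chr2	2e+07	19.8
chr2	3e+07	31
chr2	4e+07	40.2
chr2	5e+07	50.1
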