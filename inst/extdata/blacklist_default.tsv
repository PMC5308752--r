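chrom	pos	ref	alt
chr9	139390944	GC	G
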