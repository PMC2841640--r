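name	replicon	start	end	note
low_gc_region	chromosome	2110297	2163576	53-kb low-GC region (50.1% GC vs 66.7% for the rest of the chromosome); putative DNA secretion system
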