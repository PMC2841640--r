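set	group	pka
embl	Nterm	8.6
embl	Cterm	3.6
embl	C	8.5
embl	D	3.9
embl	E	4.1
embl	H	6.5
embl	K	10.8
embl	R	12.5
embl	Y	10.1
expasy	Nterm	7.5
expasy	Cterm	3.55
expasy	C	9.0
expasy	D	4.05
expasy	E	4.45
expasy	H	5.98
expasy	K	10.0
expasy	R	12.0
expasy	Y	10.0
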