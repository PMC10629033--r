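# toy two-layer network: layers 1-2, interlayer id 3
a	b	1
a	c	1
b	c	1
d	e	2
d	f	2
e	f	2
a	d	3
c	f	3
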