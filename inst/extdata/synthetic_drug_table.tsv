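ndc	generic_name	therapeutic_group	therapeutic_class	therapeutic_subclass
00071015523	atorvastatin	C	V	L
00071015640	atorvastatin	C	V	L
00093505698	donepezil	N	C	H
00378180110	memantine	N	C	H
00185012501	alprazolam	C	H	D
00185012601	diazepam	C	H	D
00054327099	metformin	D	B	
00054852799	lisinopril	C	V	
00172392870	omeprazole	G	I	A
00904629261	unclassified elixir			
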