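# Published consensus-codon assignment for the "HIGH-Motif 2" ancestral
# coding region. Class I columns 272-285 paired antiparallel with Class II
# columns 701-688; Class II codons are printed in pairing orientation.
# classI_aa / classII_aa: consensus residues of the structure-based MSAs
# ("+" marks a gap consensus).
classI_column	classI_aa	classI_codon	classII_codon	classII_aa	classII_column
272	G	xxx	xxx	N	701
273	P	xxx	GAx	E	700
274	Y	xAx	xAx	N	699
275	P	xCx	xGx	R	698
276	S	Axx	TTx	F	697
277	G	Gxx	xxx	C	696
278	+	xxx	xxx	P	695
279	S	xxx	xxx	G	694
280	L	xTx	xxx	G	693
281	H	CAx	xTx	F	692
282	I	xTx	xxx	E	691
283	G	GGx	xxx	A	690
284	H	xAx	xTx	M	689
285	A	xxx	xxx	R	688
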