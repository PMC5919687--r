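# Published consensus-codon assignment for the "KMSKS-Motif 1" ancestral
# coding region. Columns with low occupancy on both strands were omitted in
# the source layout, so positions are not consecutive; Class II codons are
# printed in pairing orientation.
classI_column	classI_aa	classI_codon	classII_codon	classII_aa	classII_column
1352	H	xxx	xxx	M	371
1356	G	xxx	CCx	P	370
1360	L	xxx	xxx	T	368
1361	L	xTx	xxx	E	366
1414	K	AAx	xTx	V	365
1415	M	xTx	xxx	E	364
1416	S	xxx	xxx	M	363
1417	K	Axx	xxx	F	362
1418	+	xxx	GGx	G	361
1444	L	xxx	xxx	R	352
1450	G	xxx	xxx	D	348
1452	N	xxx	xxx	L	347
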