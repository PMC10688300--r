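table_id	codon	aa	start
1	AAA	K	0
1	AAC	N	0
1	AAG	K	0
1	AAT	N	0
1	ACA	T	0
1	ACC	T	0
1	ACG	T	0
1	ACT	T	0
1	AGA	R	0
1	AGC	S	0
1	AGG	R	0
1	AGT	S	0
1	ATA	I	0
1	ATC	I	0
1	ATG	M	1
1	ATT	I	0
1	CAA	Q	0
1	CAC	H	0
1	CAG	Q	0
1	CAT	H	0
1	CCA	P	0
1	CCC	P	0
1	CCG	P	0
1	CCT	P	0
1	CGA	R	0
1	CGC	R	0
1	CGG	R	0
1	CGT	R	0
1	CTA	L	0
1	CTC	L	0
1	CTG	L	1
1	CTT	L	0
1	GAA	E	0
1	GAC	D	0
1	GAG	E	0
1	GAT	D	0
1	GCA	A	0
1	GCC	A	0
1	GCG	A	0
1	GCT	A	0
1	GGA	G	0
1	GGC	G	0
1	GGG	G	0
1	GGT	G	0
1	GTA	V	0
1	GTC	V	0
1	GTG	V	0
1	GTT	V	0
1	TAA	*	0
1	TAC	Y	0
1	TAG	*	0
1	TAT	Y	0
1	TCA	S	0
1	TCC	S	0
1	TCG	S	0
1	TCT	S	0
1	TGA	*	0
1	TGC	C	0
1	TGG	W	0
1	TGT	C	0
1	TTA	L	0
1	TTC	F	0
1	TTG	L	1
1	TTT	F	0
2	AAA	K	0
2	AAC	N	0
2	AAG	K	0
2	AAT	N	0
2	ACA	T	0
2	ACC	T	0
2	ACG	T	0
2	ACT	T	0
2	AGA	*	0
2	AGC	S	0
2	AGG	*	0
2	AGT	S	0
2	ATA	M	1
2	ATC	I	1
2	ATG	M	1
2	ATT	I	1
2	CAA	Q	0
2	CAC	H	0
2	CAG	Q	0
2	CAT	H	0
2	CCA	P	0
2	CCC	P	0
2	CCG	P	0
2	CCT	P	0
2	CGA	R	0
2	CGC	R	0
2	CGG	R	0
2	CGT	R	0
2	CTA	L	0
2	CTC	L	0
2	CTG	L	0
2	CTT	L	0
2	GAA	E	0
2	GAC	D	0
2	GAG	E	0
2	GAT	D	0
2	GCA	A	0
2	GCC	A	0
2	GCG	A	0
2	GCT	A	0
2	GGA	G	0
2	GGC	G	0
2	GGG	G	0
2	GGT	G	0
2	GTA	V	0
2	GTC	V	0
2	GTG	V	1
2	GTT	V	0
2	TAA	*	0
2	TAC	Y	0
2	TAG	*	0
2	TAT	Y	0
2	TCA	S	0
2	TCC	S	0
2	TCG	S	0
2	TCT	S	0
2	TGA	W	0
2	TGC	C	0
2	TGG	W	0
2	TGT	C	0
2	TTA	L	0
2	TTC	F	0
2	TTG	L	0
2	TTT	F	0
4	AAA	K	0
4	AAC	N	0
4	AAG	K	0
4	AAT	N	0
4	ACA	T	0
4	ACC	T	0
4	ACG	T	0
4	ACT	T	0
4	AGA	R	0
4	AGC	S	0
4	AGG	R	0
4	AGT	S	0
4	ATA	I	1
4	ATC	I	1
4	ATG	M	1
4	ATT	I	1
4	CAA	Q	0
4	CAC	H	0
4	CAG	Q	0
4	CAT	H	0
4	CCA	P	0
4	CCC	P	0
4	CCG	P	0
4	CCT	P	0
4	CGA	R	0
4	CGC	R	0
4	CGG	R	0
4	CGT	R	0
4	CTA	L	0
4	CTC	L	0
4	CTG	L	1
4	CTT	L	0
4	GAA	E	0
4	GAC	D	0
4	GAG	E	0
4	GAT	D	0
4	GCA	A	0
4	GCC	A	0
4	GCG	A	0
4	GCT	A	0
4	GGA	G	0
4	GGC	G	0
4	GGG	G	0
4	GGT	G	0
4	GTA	V	0
4	GTC	V	0
4	GTG	V	1
4	GTT	V	0
4	TAA	*	0
4	TAC	Y	0
4	TAG	*	0
4	TAT	Y	0
4	TCA	S	0
4	TCC	S	0
4	TCG	S	0
4	TCT	S	0
4	TGA	W	0
4	TGC	C	0
4	TGG	W	0
4	TGT	C	0
4	TTA	L	1
4	TTC	F	0
4	TTG	L	1
4	TTT	F	0
5	AAA	K	0
5	AAC	N	0
5	AAG	K	0
5	AAT	N	0
5	ACA	T	0
5	ACC	T	0
5	ACG	T	0
5	ACT	T	0
5	AGA	S	0
5	AGC	S	0
5	AGG	S	0
5	AGT	S	0
5	ATA	M	1
5	ATC	I	1
5	ATG	M	1
5	ATT	I	1
5	CAA	Q	0
5	CAC	H	0
5	CAG	Q	0
5	CAT	H	0
5	CCA	P	0
5	CCC	P	0
5	CCG	P	0
5	CCT	P	0
5	CGA	R	0
5	CGC	R	0
5	CGG	R	0
5	CGT	R	0
5	CTA	L	0
5	CTC	L	0
5	CTG	L	0
5	CTT	L	0
5	GAA	E	0
5	GAC	D	0
5	GAG	E	0
5	GAT	D	0
5	GCA	A	0
5	GCC	A	0
5	GCG	A	0
5	GCT	A	0
5	GGA	G	0
5	GGC	G	0
5	GGG	G	0
5	GGT	G	0
5	GTA	V	0
5	GTC	V	0
5	GTG	V	1
5	GTT	V	0
5	TAA	*	0
5	TAC	Y	0
5	TAG	*	0
5	TAT	Y	0
5	TCA	S	0
5	TCC	S	0
5	TCG	S	0
5	TCT	S	0
5	TGA	W	0
5	TGC	C	0
5	TGG	W	0
5	TGT	C	0
5	TTA	L	0
5	TTC	F	0
5	TTG	L	1
5	TTT	F	0
9	AAA	N	0
9	AAC	N	0
9	AAG	K	0
9	AAT	N	0
9	ACA	T	0
9	ACC	T	0
9	ACG	T	0
9	ACT	T	0
9	AGA	S	0
9	AGC	S	0
9	AGG	S	0
9	AGT	S	0
9	ATA	I	0
9	ATC	I	0
9	ATG	M	1
9	ATT	I	0
9	CAA	Q	0
9	CAC	H	0
9	CAG	Q	0
9	CAT	H	0
9	CCA	P	0
9	CCC	P	0
9	CCG	P	0
9	CCT	P	0
9	CGA	R	0
9	CGC	R	0
9	CGG	R	0
9	CGT	R	0
9	CTA	L	0
9	CTC	L	0
9	CTG	L	0
9	CTT	L	0
9	GAA	E	0
9	GAC	D	0
9	GAG	E	0
9	GAT	D	0
9	GCA	A	0
9	GCC	A	0
9	GCG	A	0
9	GCT	A	0
9	GGA	G	0
9	GGC	G	0
9	GGG	G	0
9	GGT	G	0
9	GTA	V	0
9	GTC	V	0
9	GTG	V	1
9	GTT	V	0
9	TAA	*	0
9	TAC	Y	0
9	TAG	*	0
9	TAT	Y	0
9	TCA	S	0
9	TCC	S	0
9	TCG	S	0
9	TCT	S	0
9	TGA	W	0
9	TGC	C	0
9	TGG	W	0
9	TGT	C	0
9	TTA	L	0
9	TTC	F	0
9	TTG	L	0
9	TTT	F	0
11	AAA	K	0
11	AAC	N	0
11	AAG	K	0
11	AAT	N	0
11	ACA	T	0
11	ACC	T	0
11	ACG	T	0
11	ACT	T	0
11	AGA	R	0
11	AGC	S	0
11	AGG	R	0
11	AGT	S	0
11	ATA	I	1
11	ATC	I	1
11	ATG	M	1
11	ATT	I	1
11	CAA	Q	0
11	CAC	H	0
11	CAG	Q	0
11	CAT	H	0
11	CCA	P	0
11	CCC	P	0
11	CCG	P	0
11	CCT	P	0
11	CGA	R	0
11	CGC	R	0
11	CGG	R	0
11	CGT	R	0
11	CTA	L	0
11	CTC	L	0
11	CTG	L	1
11	CTT	L	0
11	GAA	E	0
11	GAC	D	0
11	GAG	E	0
11	GAT	D	0
11	GCA	A	0
11	GCC	A	0
11	GCG	A	0
11	GCT	A	0
11	GGA	G	0
11	GGC	G	0
11	GGG	G	0
11	GGT	G	0
11	GTA	V	0
11	GTC	V	0
11	GTG	V	1
11	GTT	V	0
11	TAA	*	0
11	TAC	Y	0
11	TAG	*	0
11	TAT	Y	0
11	TCA	S	0
11	TCC	S	0
11	TCG	S	0
11	TCT	S	0
11	TGA	*	0
11	TGC	C	0
11	TGG	W	0
11	TGT	C	0
11	TTA	L	0
11	TTC	F	0
11	TTG	L	1
11	TTT	F	0
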