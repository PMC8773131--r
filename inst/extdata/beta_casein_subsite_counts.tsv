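enzyme	subsite	amino_acid	cleaved
PRA205	P1	A	2
PRA205	P1	G	1
PRA205	P1	V	3
PRA205	P1	L	10
PRA205	P1	I	1
PRA205	P1	M	5
PRA205	P1	T	2
PRA205	P1	S	8
PRA205	P1	Q	10
PRA205	P1	N	4
PRA205	P1	P	8
PRA205	P1	R	2
PRA205	P1	K	5
PRA205	P1	H	1
PRA205	P1	E	3
PRA205	P1	D	1
PRA205	P1	F	2
PRA205	P1	Y	1
PRA205	P1	W	1
PRA205	P1	C	0
PRA205	P1prime	A	4
PRA205	P1prime	G	3
PRA205	P1prime	V	9
PRA205	P1prime	L	10
PRA205	P1prime	I	4
PRA205	P1prime	M	2
PRA205	P1prime	T	2
PRA205	P1prime	S	7
PRA205	P1prime	Q	2
PRA205	P1prime	N	2
PRA205	P1prime	P	4
PRA205	P1prime	R	1
PRA205	P1prime	K	4
PRA205	P1prime	H	3
PRA205	P1prime	E	2
PRA205	P1prime	D	4
PRA205	P1prime	F	4
PRA205	P1prime	Y	2
PRA205	P1prime	W	1
PRA205	P1prime	C	0
2006	P1	A	3
2006	P1	G	2
2006	P1	V	3
2006	P1	L	9
2006	P1	I	1
2006	P1	M	4
2006	P1	T	1
2006	P1	S	7
2006	P1	Q	10
2006	P1	N	3
2006	P1	P	5
2006	P1	R	2
2006	P1	K	6
2006	P1	H	1
2006	P1	E	5
2006	P1	D	0
2006	P1	F	2
2006	P1	Y	1
2006	P1	W	1
2006	P1	C	0
2006	P1prime	A	5
2006	P1prime	G	3
2006	P1prime	V	8
2006	P1prime	L	8
2006	P1prime	I	3
2006	P1prime	M	2
2006	P1prime	T	1
2006	P1prime	S	7
2006	P1prime	Q	3
2006	P1prime	N	1
2006	P1prime	P	4
2006	P1prime	R	1
2006	P1prime	K	5
2006	P1prime	H	3
2006	P1prime	E	2
2006	P1prime	D	4
2006	P1prime	F	3
2006	P1prime	Y	2
2006	P1prime	W	1
2006	P1prime	C	0
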