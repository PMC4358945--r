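No	Sequence	IC50_uM
1	ARHPH	0.0156
2	DIGYY	3.4
3	DKIHP	113.1
4	DYVGN	0.72
5	ERYPI	8.76
6	EVPKA	324.77
7	IKYGD	4.5
8	KDERF	848
9	KDYRL	26.5
10	LDIQK	27.6
11	LPYPY	28.9
12	LVQGS	43.7
13	MRWRD	2.1
14	RINKK	0.0183
15	RYLGY	0.71
16	SLPQN	0.00948
17	TVVPG	2.2
18	TYKEE	0.0186
19	TYLGS	0.86
20	VKQGF	20.3
21	VLIVP	1.69
22	WVPSV	0.501
23	YTAGV	23.38
24	YVVFK	44
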