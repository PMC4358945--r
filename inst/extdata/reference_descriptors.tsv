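No	ALogP	MR	Apol	LogD	Rotbond	Ring	AR	HBA	HBD	PSA
1	-3.40648	150.01	21842.80	-5.211	16	3	2	8	9	0.472
2	-0.5315	148.186	23371.50	-3.62	17	2	2	10	7	0.417
3	-1.57883	140.478	21007.90	-6.343	18	2	1	9	6	0.43
4	0.1427	125.13	20031.40	-6.645	16	1	1	10	7	0.496
5	-4.17411	162.498	24053.20	-4.59	19	2	1	9	8	0.43
6	-1.75544	123.385	18340.80	-6.673	16	1	0	8	5	0.423
7	1.17668	137.363	21169.30	-5.804	19	1	1	9	7	0.438
8	-7.64934	157.324	24572.40	-9.119	24	1	1	10	9	0.492
9	-0.97576	165.622	24679.50	-6.381	23	1	1	9	10	0.46
10	-1.4409	141.829	20908.70	-6.554	22	0	0	9	7	0.444
11	-0.18578	165.819	24392.10	-0.486	13	4	2	8	5	0.32
12	2.40026	116.474	16937.50	-5.206	16	0	0	8	7	0.459
13	-1.4177	186.874	28111.80	-5.953	24	2	2	9	12	0.502
14	4.6319	160.264	22613.60	-7.87	25	0	0	7	11	0.482
15	1.46736	169.636	25104.30	-2.379	19	2	2	8	10	0.419
16	0.616643	127.519	18710.70	-6.491	16	1	0	9	7	0.486
17	1.08715	111.291	15909.40	-3.97	11	1	0	7	5	0.392
18	-6.51692	146.046	23291.50	-8.625	22	1	1	12	8	0.483
19	2.27823	127.141	19082.70	-4.319	15	1	1	9	8	0.439
20	0.263857	141.365	20960.90	-5.071	19	1	1	7	7	0.418
21	-0.2278	137.092	18644.10	-0.405	14	1	0	6	4	0.299
22	-10.8299	147.072	21425.80	-1.896	13	3	2	7	6	0.354
23	-0.94115	120.919	18224.60	-3.266	13	1	1	8	7	0.424
24	-1.6435	168.555	24814.30	-0.956	19	2	2	7	7	0.34
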