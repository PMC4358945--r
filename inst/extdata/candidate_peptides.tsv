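Sequence	Protease	Subunit	ALogP	MR	Apol	LogD	Rotbond	Ring	AR	HBA	HBD	PSA	BPNN_output	Predicted_IC50_uM
AAWGK	trypsin	alpha	-4.704	130.843	19654.10	-4.702	15	2	2	6	7	0.414	0.5093	2.5513
AHRYH	pepsin	beta	-5.548	168.635	25184.50	-4.691	19	3	3	9	11	0.470	0.7990	0.0938
FTPVL	pepsin	beta	-1.547	145.081	20818.60	-1.54	14	2	1	7	5	0.326	0.4534	4.8240
GHGAK	trypsin	alpha	-7.589	107.89	16291.60	-6.806	15	1	1	7	7	0.487	0.4983	2.8916
PTTKT	pepsin	alpha	-7.283	125.207	18110.90	-7.28	16	1	0	9	9	0.460	0.2890	31.4255
TSKYR	pepsin	alpha	-6.927	157.139	23078.30	-6.915	21	1	1	9	12	0.492	0.3204	21.9784
WTQRF	pepsin	beta	-3.789	186.729	27793.80	-2.911	21	3	3	8	11	0.439	0.8501	0.0524
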