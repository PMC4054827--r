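pair_id	zygosity	chorionicity	twin1_sex	twin2_sex	gestational_age	birth_weight_discordance_pct	samples_removed
1016	MZ	DC	M	M	37	5.4	T2_18
1022	MZ	MC	M	M	38	12.4	T1_18,T2_18
1024	MZ	DC	F	F	37	12.1	T2_B
1032	DZ	DC	F	F	37	43.3	T1_18
1035	MZ	MC	F	F	35	30.8	
1042	DZ	DC	M	M	30	19.8	
1046	MZ	DC	M	M	37	6.2	
1057	DZ	DC	M	M	37	13.3	
1058	MZ	DC	M	M	36	22.0	
1072	DZ	DC	F	F	37	14.5	
1107	MZ	MC	F	F	33	8.1	T1_18
1126	MZ	MC	F	F	32	27.3	T2_18
2034	MZ	DC	F	F	36	3.6	
3006	DZ	DC	M	M	37	3.6	
3014	MZ	MC	M	M	36	18.0	
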