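target_id	cohort	variable	level	statin	no_statin	printed_p
t1	discovery	sex	men	80	314	0.002
t1	discovery	sex	women	58	403	0.002
t2	discovery	education	low	55	257	0.36
t2	discovery	education	middle	61	309	0.36
t2	discovery	education	high	22	151	0.36
t3	discovery	smoking	current	17	102	0.427
t3	discovery	smoking	previous	66	302	0.427
t3	discovery	smoking	never	54	312	0.427
t4	discovery	physical_activity	regular_2h	60	260	0.306
t4	discovery	physical_activity	regular_1h	40	240	0.306
t4	discovery	physical_activity	irregular_1h	19	89	0.306
t4	discovery	physical_activity	little_or_not	19	128	0.306
t5	discovery	hypertension	yes	95	306	6e-9
t5	discovery	hypertension	no	41	411	6e-9
t6	discovery	diabetes	yes	31	41	9e-11
t6	discovery	diabetes	no	107	676	9e-11
t7	discovery	myocardial_infarction	yes	19	7	1e-15
t7	discovery	myocardial_infarction	no	119	710	1e-15
t8	discovery	stroke	yes	15	8	9e-11
t8	discovery	stroke	no	123	709	9e-11
t9	discovery	cancer	yes	20	82	0.31
t9	discovery	cancer	no	118	635	0.31
t10	replication	sex	men	146	391	0.858
t10	replication	sex	women	150	392	0.858
t11	replication	education	low	181	512	0.033
t11	replication	education	middle	71	198	0.033
t11	replication	education	high	44	73	0.033
t12	replication	smoking	current	16	33	0.124
t12	replication	smoking	previous	135	313	0.124
t12	replication	smoking	never	145	437	0.124
t13	replication	physical_activity	regular_2h	85	219	0.86
t13	replication	physical_activity	regular_1h	67	193	0.86
t13	replication	physical_activity	irregular_1h	38	106	0.86
t13	replication	physical_activity	little_or_not	106	264	0.86
t14	replication	hypertension	yes	239	551	0.002
t14	replication	hypertension	no	53	209	0.002
t15	replication	diabetes	yes	75	116	6e-5
t15	replication	diabetes	no	221	665	6e-5
t16	replication	myocardial_infarction	yes	68	43	3e-17
t16	replication	myocardial_infarction	no	228	740	3e-17
t17	replication	stroke	yes	37	58	0.008
t17	replication	stroke	no	259	725	0.008
t18	replication	cancer	yes	36	116	0.264
t18	replication	cancer	no	260	667	0.264
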