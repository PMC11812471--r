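rsid	chrom	pos	ref	alt	risk_allele	odds_ratio	locus	freq
rs10922109	1	196704632	C	A	C	2.4	CFH	0.55
rs3750846	10	124215565	T	C	C	2.8	ARMS2/HTRA1	0.3
rs187328863	1	196380158	C	T	T	1.47	CFH	0.12
rs114092250	5	35494448	A	T	T	0.71	PRLR/SPEF2	0.85
rs10781182	9	76617720	G	A	A	1.12	MIR6130/RORB	0.4
rs67538026	19	1031438	G	C	C	0.9	CNN2	0.7
rs201459901	20	56653724	T	TA	TA	0.76	C20orf85	0.8
rs90000001	1	1000137	C	G	G	1.16	SYNTH01	0.46
rs90000002	2	1000274	G	T	T	1.053	SYNTH02	0.254
rs90000003	3	1000411	T	A	A	1.05	SYNTH03	0.475
rs90000004	4	1000548	A	C	C	1.255	SYNTH04	0.214
rs90000005	5	1000685	C	G	G	1.269	SYNTH05	0.531
rs90000006	6	1000822	G	T	T	1.212	SYNTH06	0.485
rs90000007	7	1000959	T	A	A	1.299	SYNTH07	0.422
rs90000008	8	1001096	A	C	C	1.095	SYNTH08	0.514
rs90000009	9	1001233	C	G	C	0.812	SYNTH09	0.303
rs90000010	10	1001370	G	T	T	1.311	SYNTH10	0.528
rs90000011	11	1001507	T	A	A	1.343	SYNTH11	0.591
rs90000012	12	1001644	A	C	C	1.193	SYNTH12	0.234
rs90000013	13	1001781	C	G	G	1.198	SYNTH13	0.269
rs90000014	14	1001918	G	T	T	1.171	SYNTH14	0.364
rs90000015	15	1002055	T	A	A	1.05	SYNTH15	0.209
rs90000016	16	1002192	A	C	C	1.383	SYNTH16	0.346
rs90000017	17	1002329	C	G	G	1.241	SYNTH17	0.239
rs90000018	18	1002466	G	T	G	0.842	SYNTH18	0.56
rs90000019	19	1002603	T	A	A	1.41	SYNTH19	0.584
rs90000020	20	1002740	A	C	C	1.085	SYNTH20	0.215
rs90000021	21	1002877	C	G	G	1.05	SYNTH21	0.532
rs90000022	22	1003014	G	T	T	1.05	SYNTH22	0.173
rs90000023	1	1003151	T	A	A	1.168	SYNTH23	0.494
rs90000024	2	1003288	A	C	C	1.318	SYNTH24	0.309
rs90000025	3	1003425	C	G	G	1.228	SYNTH25	0.525
rs90000026	4	1003562	G	T	T	1.21	SYNTH26	0.411
rs90000027	5	1003699	T	A	T	0.741	SYNTH27	0.574
rs90000028	6	1003836	A	C	C	1.053	SYNTH28	0.527
rs90000029	7	1003973	C	G	G	1.436	SYNTH29	0.433
rs90000030	8	1004110	G	T	T	1.05	SYNTH30	0.511
rs90000031	9	1004247	T	A	A	1.206	SYNTH31	0.415
rs90000032	10	1004384	A	C	C	1.364	SYNTH32	0.266
rs90000033	11	1004521	C	G	G	1.141	SYNTH33	0.26
rs90000034	12	1004658	G	T	T	1.05	SYNTH34	0.484
rs90000035	13	1004795	T	A	A	1.16	SYNTH35	0.229
rs90000036	14	1004932	A	C	A	0.69	SYNTH36	0.524
rs90000037	15	1005069	C	G	G	1.244	SYNTH37	0.434
rs90000038	16	1005206	G	T	T	1.247	SYNTH38	0.354
rs90000039	17	1005343	T	A	A	1.232	SYNTH39	0.384
rs90000040	18	1005480	A	C	C	1.45	SYNTH40	0.207
rs90000041	19	1005617	C	G	G	1.169	SYNTH41	0.246
rs90000042	20	1005754	G	T	T	1.13	SYNTH42	0.435
rs90000043	21	1005891	T	A	A	1.283	SYNTH43	0.248
rs90000044	22	1006028	A	C	C	1.28	SYNTH44	0.209
rs90000045	1	1006165	C	G	C	0.952	SYNTH45	0.418
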