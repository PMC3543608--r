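index	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
SYNIDX01	1.967	-1.806	-2.619	-0.397	4.072	0.344	-0.161	1.048	2.597	1.524	0.926	-2.185	2.006	-0.303	-5.697	4.288	-4.98	-0.193	0.288	-0.024
SYNIDX02	1.491	-2.263	1.916	2.53	2.684	-0.157	1.423	0.093	2.095	1.639	1.58	1.096	-0.81	0.944	-1.131	2.191	0.751	-2.39	1.092	-1.256
SYNIDX03	-0.205	-0.692	-2.712	-1.962	0.645	0.777	0.838	-0.61	-0.79	0.358	-0.063	-0.38	0.251	-0.224	-1.484	2.773	-2.556	0.872	1.26	1.109
SYNIDX04	-0.476	2.178	-5.418	-1.484	0.804	2.743	2.244	-5.07	-3.033	1.639	-9.313	4.679	-1.141	0.835	-3.331	0.085	4.137	-1.651	0.617	-0.799
SYNIDX05	1.723	-4.281	6.834	5.292	2.267	-1.489	2.243	2.137	5.111	0.526	7.91	-0.373	-2.27	1.623	4.343	3.146	0.579	-1.682	3.678	-1.613
SYNIDX06	2.957	-2.403	1.751	2.122	2.614	-1.02	-1.259	2.868	3.953	1.982	2.184	-1.895	2.509	-0.199	-3.779	1.114	-2.589	-0.879	-1.577	-1.416
SYNIDX07	-0.164	0.831	-5.619	-4.678	-0.056	0.432	-0.285	-0.522	-3.658	0.414	-2.946	-1.104	1.851	-0.76	-5.124	2.104	-4.623	0.743	-0.877	1.088
SYNIDX08	-1.402	0.479	0.226	-0.554	-1.821	-0.148	0.918	-0.666	-3.16	-0.835	-0.795	0.938	-1.805	0.662	2.311	-1.705	1.934	-0.94	0.571	-0.521
SYNIDX09	-1.795	0.874	-3.493	-3.193	-0.8	1.048	1.021	-2.337	-3.303	-0.289	0.604	1.019	-1.94	-0.379	0.461	1.939	-1.623	0.786	1.6	0.837
SYNIDX10	0.534	0.598	-0.59	1.204	0.866	2.168	3.258	-3.211	-0.01	1.011	-3.076	4.226	-2.916	1.185	0.367	0.118	4.294	-2.812	2.268	-0.787
SYNIDX11	-0.439	-0.659	2.305	0.951	-2.052	-1.345	-0.868	2.025	-1.293	-0.818	1.541	-0.83	-0.567	-0.087	1.052	-1.424	0.573	-0.593	-0.803	-0.045
SYNIDX12	-0.471	1.864	3.007	3.576	-0.773	1.027	1.624	-2.65	-0.278	1.085	-4.743	5.278	-2.888	0.975	2.442	-4.283	8.217	-2.219	0.668	-2.295
SYNIDX13	-1.676	1.961	-3.151	-3.627	-4.452	-1.233	-2.177	1.785	-6.011	-1.013	-2.016	-1.325	1.422	-1.356	-2.286	-1.836	-1.659	-0.501	-3.006	0.163
SYNIDX14	-0.423	0.214	-1.564	-3.343	-2.037	-1.549	-2.474	2.881	-3.496	-0.066	-1.351	-1.928	2.036	-0.989	-4.453	-0.925	-3.511	-0.529	-3.179	-0.347
SYNIDX15	-2.813	2.068	1.102	-1.033	-3.723	-0.457	-0.094	-0.687	-4.458	-1.075	-3.039	1.901	-1.291	0.543	1.972	-4.428	3.657	-1.394	-1.297	0.073
SYNIDX16	1.78	-3.127	2.805	2.297	3.336	-1.038	0.863	2.184	5	1.457	6.66	-2.053	0.456	-0.043	0.796	3.74	-3.677	0.561	2.167	0.072
SYNIDX17	-2.815	4.05	-2.938	-2.695	-3.645	0.814	0.184	-3.613	-3.954	-0.93	-6.113	2.307	-1.316	-0.128	1.926	-3.652	3.516	1.48	-0.696	0.76
SYNIDX18	1.525	-1.335	4.122	6.594	3.473	2.152	3.498	-2.991	5.671	1.352	-0.29	4.019	-2.7	2.114	2.435	0.007	7.142	-2.498	3.211	-3.099
SYNIDX19	0.052	-1.003	4.447	1.577	-2.836	-3.043	-4.052	5.156	0.604	-1.389	3.958	-3.35	1.979	-0.541	1.998	-2.409	-1.66	1.279	-2.972	-0.086
SYNIDX20	-0.712	2.401	-2.954	-3.204	-0.901	-0.149	-2.809	0.894	-0.374	-0.441	-2.5	-2.064	2.909	-1.956	-2.474	-0.413	-3.689	2.759	-2.585	1.6
SYNIDX21	-1.286	2.225	0.813	2.913	0.248	3.353	4.63	-6.633	0.856	-0.332	-3.891	6.442	-5.151	1.685	5.24	-2.883	9.003	-1.217	4.034	-1.278
SYNIDX22	0.981	-0.825	-1.609	0.391	2.485	1.118	1.123	-1.913	1.283	0.884	0.29	0.454	0.063	-0.096	-1.157	2.994	-0.545	0.804	2.182	-0.291
SYNIDX23	-0.145	2.232	4.466	2.73	-2.077	-0.606	-2.937	0.535	2.991	-1.824	1.151	-1.042	0.551	-0.939	5.775	-4.726	2.792	3.682	-0.916	0.438
SYNIDX24	0.673	1.229	2.888	3.16	0.481	0.47	-1.082	-0.816	4.751	-0.251	0.49	0.986	0.106	-0.706	3.849	-2.073	3.323	2.507	0.452	0.084
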