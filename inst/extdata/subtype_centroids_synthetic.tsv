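gene	luminal_papillary	luminal_infiltrated	luminal	basal_squamous	neuronal
SG001	7.742	5.412	8.025	2.013	4.649
SG002	3.871	4.278	5.516	2.059	2.856
SG003	5.726	6.516	5.177	5.249	5.326
SG004	6.266	3.547	4.758	3.007	4.275
SG005	5.809	2.263	2.611	4.996	6.18
SG006	4.788	5.866	6.224	4.143	7.865
SG007	8.023	3.377	4.566	3.773	3.015
SG008	4.811	7.888	4.634	0.951	5.909
SG009	9.037	4.137	6.867	2.551	5.17
SG010	4.875	6.311	6.644	5.359	6.791
SG011	7.61	5.644	7.784	6.135	4.54
SG012	9.573	3.432	4.048	4.014	6.673
SG013	2.222	8.151	6.301	5	1.51
SG014	4.442	6.286	7.782	7.246	8.379
SG015	4.733	5.18	2.778	7.88	6.73
SG016	6.272	5.553	3.278	2.806	4.698
SG017	4.431	6.359	2.737	4.765	2.102
SG018	-0.313	5.18	2.082	7.403	6.286
SG019	0.119	-0.986	5.16	4.061	5.966
SG020	7.64	5.57	6.306	4.895	4.987
SG021	4.387	4.266	7.402	4.828	5.303
SG022	1.437	5.37	7.09	3.225	3.832
SG023	4.656	6.164	2.994	4.111	5.738
SG024	7.429	7.799	8.697	4.941	5.589
SG025	8.79	3.545	3.666	4.172	4.441
SG026	4.139	7.605	5.211	7.227	2.328
SG027	4.485	5.672	4.155	4.038	6.401
SG028	1.474	7.077	4.755	4.134	6.108
SG029	5.92	6.841	5.376	6.394	3.327
SG030	3.72	6.442	5.238	2.887	1.811
SG031	5.911	2.914	4.95	4.919	5.41
SG032	6.41	4.82	5.216	1.897	4.31
SG033	7.07	6.247	4.029	7.334	5.505
SG034	3.782	3.093	3.992	4.453	2.412
SG035	6.01	3.914	1.678	4.064	3.082
SG036	1.566	6.162	4.235	2.523	7.172
SG037	3.431	6.536	3.975	4.984	5.808
SG038	3.298	5.928	10.404	3.399	6.173
SG039	0.172	3.228	2.276	3.933	8.63
SG040	5.072	2.8	5.275	7.575	5.258
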