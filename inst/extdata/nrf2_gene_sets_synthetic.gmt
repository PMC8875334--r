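antioxidant proteins	synthetic placeholder membership; per-set sizes follow the published table	g0324	g0167	g0129	g0418	g0471	g0299	g0270	g0466	g0187	g0307	g0481	g0085	g0277	g0362	g0438	g0330	g0263	g0329
phase I and II metabolizing enzymes	synthetic placeholder membership; per-set sizes follow the published table	g0079	g0213	g0037	g0105	g0217	g0366	g0165	g0290	g0487	g0382	g0089	g0428	g0463	g0289	g0340	g0419	g0326	g0485	g0042	g0422	g0111	g0404	g0412	g0020	g0044	g0377	g0343	g0070	g0121	g0040	g0172	g0025	g0375	g0248	g0198	g0378	g0039	g0435	g0298	g0390	g0280	g0160	g0014	g0130	g0045	g0402	g0022	g0206
chaperone and stress response proteins	synthetic placeholder membership; per-set sizes follow the published table	g0230	g0193	g0371	g0104	g0493	g0255	g0430	g0431	g0103	g0331	g0013	g0296	g0478	g0176	g0345	g0279	g0110	g0084	g0359	g0029	g0141	g0252	g0406	g0221	g0108	g0304	g0033	g0486	g0149	g0287	g0102	g0145	g0483	g0456	g0339	g0118	g0346	g0409	g0107	g0064	g0224	g0426	g0316
phase III detoxifying proteins	synthetic placeholder membership; per-set sizes follow the published table	g0051	g0411	g0475	g0138
ubiquitination and proteasomal degradation	synthetic placeholder membership; per-set sizes follow the published table	g0498	g0495	g0282	g0143	g0285
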