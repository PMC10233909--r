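genus	H	R	L	B	S	N	category
Saprospiraceae_unc	3.96	10.15	4.28	1.79	0.08	0.2	core
Portibacter	1	3.79	1.21	0.43	0.02	0.05	core
Lewinella	0.96	0.65	2	0.88	0.01	0.03	core
Algitalea	8.9	1.44	15.07	1.36	0.08	0.07	core
Microtrichaceae_unc	2.24	4.49	4.89	0.46	0.03	0.11	core
Sva0996_marine_group	1.97	9.23	4.89	0.64	0.27	0.28	core
Rubritalea	2.06	0.62	1.02	24.37	0.13	0.04	core
Rhizobiaceae_unc	1.53	5.97	9.63	0.56	0.1	0.11	core
Robiginitomaculum	1.22	0.56	0.32	0.38	0.01	0.01	core
Hellea	7.45	3.08	4.69	0.49	0.11	0.11	core
Rhodobacteraceae_unc	2.32	3.99	3.45	0.49	0.19	0.1	core
Sulfitobacter	0.68	0.97	0.64	1.04	4.52	0.07	core
Granulosicoccus	7.55	7.84	4.32	11.65	0.13	0.22	core
Leucothrix	1.69	1.13	2.81	3.1	0.04	0.05	core
Truepera	2.12	1.74	2.91	0.15	0.01	0.18	dominant
Rubidimonas	0.69	0.71	2.08	0.28	0.01	0.01	dominant
Maribacter	0.83	1.41	0.31	1.13	0.02	0.12	dominant
Tenacibaculum	0.75	0.09	0.31	3.37	0.06	0.03	dominant
Aquimarina	0.29	0.49	0.05	0.37	0.01	0.03	dominant
Roseibacillus	6.08	4.57	0.35	0.05	0.03	0.07	dominant
Erythrobacter	0.41	0.47	0.53	0.36	0	0.03	dominant
Pseudahrensia	0.66	0.51	0.27	0.63	0.02	0.09	dominant
Hyphomonadaceae_unc	2.41	0.65	0.55	0.25	0.03	0.01	dominant
Celeribacter	0.23	1.43	1.21	0.98	0.03	0.02	dominant
Planktotalea	0.61	1.41	1.28	0.72	1.79	0.05	dominant
Yoonia-Loktanella	0.17	0.43	0.81	1.01	0.03	0	dominant
Ruegeria	0.17	0.35	1.04	3.57	4.15	0.18	dominant
Acinetobacter	3.62	1.78	5.06	0.03	0.12	0.41	dominant
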