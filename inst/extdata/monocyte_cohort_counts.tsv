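panel	threshold	alpha	n	ase	gte	ratio_printed
associations	fdr	0.05	395	NA	31963	NA
associations	fdr	0.05	188	203893	16757	12.2
associations	fdr	0.05	95	127990	6879	18.6
associations	fdr	0.05	50	65258	2077	31.4
associations	fdr	0.01	395	NA	22651	NA
associations	fdr	0.01	188	155205	11101	14.0
associations	fdr	0.01	95	87523	4242	20.6
associations	fdr	0.01	50	38685	1151	33.6
associations	bonferroni	0.05	395	NA	9424	NA
associations	bonferroni	0.05	188	58078	4277	13.6
associations	bonferroni	0.05	95	23213	1439	16.1
associations	bonferroni	0.05	50	6781	390	17.4
associations	bonferroni	0.01	395	NA	8337	NA
associations	bonferroni	0.01	188	51383	3677	14.0
associations	bonferroni	0.01	95	19357	1189	16.3
associations	bonferroni	0.01	50	5191	300	17.3
snps	fdr	0.05	395	NA	24379	NA
snps	fdr	0.05	188	111978	13479	8.3
snps	fdr	0.05	95	76161	5887	12.9
snps	fdr	0.05	50	42100	1863	22.6
snps	fdr	0.01	395	NA	17975	NA
snps	fdr	0.01	188	88837	9281	9.6
snps	fdr	0.01	95	54758	3739	14.6
snps	fdr	0.01	50	26284	1064	24.7
snps	bonferroni	0.05	395	NA	8148	NA
snps	bonferroni	0.05	188	37995	3855	9.9
snps	bonferroni	0.05	95	16467	1349	12.2
snps	bonferroni	0.05	50	5037	370	13.6
snps	bonferroni	0.01	395	NA	7266	NA
snps	bonferroni	0.01	188	34131	3335	10.2
snps	bonferroni	0.01	95	13876	1119	12.4
snps	bonferroni	0.01	50	3881	284	13.7
transcripts	fdr	0.05	395	NA	5051	NA
transcripts	fdr	0.05	188	12389	3364	3.7
transcripts	fdr	0.05	95	7111	1850	3.8
transcripts	fdr	0.05	50	6447	740	8.7
transcripts	fdr	0.01	395	NA	3620	NA
transcripts	fdr	0.01	188	11914	2256	5.3
transcripts	fdr	0.01	95	6788	1158	5.9
transcripts	fdr	0.01	50	5472	423	12.9
transcripts	bonferroni	0.05	395	NA	1867	NA
transcripts	bonferroni	0.05	188	8723	1064	8.2
transcripts	bonferroni	0.05	95	4395	476	9.2
transcripts	bonferroni	0.05	50	1984	165	12.0
transcripts	bonferroni	0.01	395	NA	1712	NA
transcripts	bonferroni	0.01	188	8223	948	8.7
transcripts	bonferroni	0.01	95	3994	407	9.8
transcripts	bonferroni	0.01	50	1607	133	12.1
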