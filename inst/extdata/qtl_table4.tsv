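qtl_id	symbol	trait_name	chr	start_bp	end_bp	trait_class
103450	MOTSCT	Number of motile sperm	1	53958169	53958209	reproduction
32144	OSTEO	Osteochondrosis	2	11816213	21391792	health
32142	OSTEO	Osteochondrosis	2	12910010	21391792	health
32146	OSTEO	Osteochondrosis	2	12910010	21391792	health
32145	OSTD	Osteochondrosis dissecans	2	13028376	22500086	health
32143	OSTEO	Osteochondrosis	2	18664801	19717761	health
32147	OSTEO	Osteochondrosis	2	18664801	23235964	health
29325	OSTEO	Osteochondrosis	3	105163057	105163097	health
29326	OSTEO	Osteochondrosis	3	105546982	105547022	health
29327	OSTEO	Osteochondrosis	3	105830605	105830645	health
29306	SUSBITE	Insect bite hypersensitivity	4	43000811	43945687	health
37902	OSTD	Osteochondrosis dissecans	5	77424966	77425006	health
29287	SUSBITE	Insect bite hypersensitivity	11	22016942	22985500	health
29268	RHOD	Rhodococcus equi infection	14	3055253	3055293	health
29315	SUSBITE	Insect bite hypersensitivity	15	20012397	20994475	health
29316	SUSBITE	Insect bite hypersensitivity	15	32000266	32987009	health
29035	GPT	Guttural pouch tympany	15	53093059	53093099	health
29111	GPT	Guttural pouch tympany	15	65298904	65298944	health
29067	GPT	Guttural pouch tympany	15	78013499	78013539	health
28922	OSTEO	Osteochondrosis	16	1299549	5389006	health
29002	OSTD	Osteochondrosis dissecans	16	1299549	5389006	health
28933	OSTEO	Osteochondrosis	16	5228939	5496903	health
28999	OSTD	Osteochondrosis dissecans	16	5228939	5496903	health
28927	OSTD	Osteochondrosis dissecans	16	22275834	22702331	health
28937	OSTEO	Osteochondrosis	16	22275834	22702331	health
29006	OSTEO	Osteochondrosis	16	22275834	22702331	health
29338	RER	Recurrent exertional rhabdomyolysis	16	29314251	29314291	health
29277	RER	Recurrent exertional rhabdomyolysis	16	29349222	29349262	health
29337	RER	Recurrent exertional rhabdomyolysis	16	29349222	29349262	health
29320	SUSBITE	Insect bite hypersensitivity	19	21037979	21977304	health
29298	SUSBITE	Insect bite hypersensitivity	20	41031989	41982509	health
37895	SUSBITE	Insect bite hypersensitivity	20	41530793	42603867	health
37896	SUSBITE	Insect bite hypersensitivity	20	41530793	42603867	health
28920	SARRESI	Equine sarcoids	23	16126529	41049320	health
28921	SARRESI	Equine sarcoids	25	24227654	30109054	health
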