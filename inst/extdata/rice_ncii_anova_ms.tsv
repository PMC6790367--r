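trait	ms_males	ms_females	ms_mf	ms_rep	vf	vm	vmf	ve	h2	H2
plant_height	660	3255	70.2463	35.7881	10.8409	43.8992	12.8182	31.7917	0.5526	0.6820
heading_date	1923	10226	453	700	33.2070	105	116	105	0.3849	0.7066
panicle_length	19.6137	664	3.8945	38.1437	2.2923	1.3099	0.9210	1.1314	0.6370	0.7999
grain_length	1.6917	11.7267	0.1427	0.0690	0.0402	0.1291	0.0390	0.0257	0.7236	0.8903
grain_width	0.1143	0.7716	0.0134	0.0065	0.0026	0.0084	0.0036	0.0027	0.6395	0.8463
grain_length_to_width	0.5907	5.8445	0.0464	0.0027	0.0201	0.0454	0.0130	0.0075	0.7619	0.9127
effective_panicles	16.9616	76.0305	11.8453	54.9942	0.2229	0.4264	3.0700	2.6354	0.1022	0.5853
flower_number_per_panicle	3853	20396	1724	2293	64.8357	177	443	394	0.2245	0.6353
seed_setting_rate	7.6780	15.6134	2.6231	4.5191	0.0451	0.4212	0.6908	0.5506	0.2731	0.6776
grain_number	591051	422185	245799	3512684	612	28771	56793	75421	0.1818	0.5333
grain_weight	27.6836	148	5.3199	7.7654	0.4944	1.8636	1.4188	1.0636	0.4872	0.7803
grain_yield	272	881	152	2354	2.5328	10.0488	35.2561	46.1265	0.1339	0.5091
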