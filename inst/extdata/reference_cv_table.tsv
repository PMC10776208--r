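test_id	avg_edges_included	avg_edges_pct	rmse	r	p_perm	intra_network	inter_network	total_validated	total_validated_pct
tmt_a	514	5.2	31.61	0.388	0.01	82	344	426	4.3
tmt_b	530	5.4	71.66	0.470	0.01	74	386	460	4.6
shopping_tour	205	2.1	6.82	0.481	0.01	26	148	174	1.8
number_transcoding	64	0.6	0.99	0.411	0.01	10	38	48	0.5
digit_span_fw	30	0.3	2.43	0.123	0.13	NA	NA	NA	NA
digit_span_bw	56	0.6	2.58	0.132	0.16	NA	NA	NA	NA
corsi_fw	224	2.3	2.32	0.202	0.11	NA	NA	NA	NA
corsi_bw	319	3.2	1.99	0.433	0.01	56	208	264	2.7
word_list_immediate	440	4.4	3.08	0.570	0.01	38	336	374	3.8
word_list_delayed	272	2.7	2.38	0.525	0.01	36	200	236	2.4
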