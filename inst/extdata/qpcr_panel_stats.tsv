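panel	gene	n_wt	mean_wt	sd_wt	n_hom	mean_hom	sd_hom	p
array_confirmation	Chrna1	3	1.00	0.00	3	0.72	0.10	0.28
array_confirmation	Gtf2e2	5	1.01	0.01	5	1.08	0.13	0.84
array_confirmation	Rasd2	5	1.01	0.01	5	2.06	0.54	0.03
array_confirmation	Odf3b	5	1.02	0.01	5	2.51	0.63	0.03
array_confirmation	Dynlrb2	5	1.01	0.01	5	3.12	1.02	0.03
array_confirmation	Meig1	5	1.01	0.01	5	3.41	0.72	0.03
array_confirmation	Bhlhe40	6	1.02	0.01	6	0.75	0.15	0.02
array_confirmation	Homer1	6	0.99	0.05	6	0.85	0.23	0.28
array_confirmation	Morn5	6	1.02	0.01	6	2.72	0.99	0.02
array_confirmation	Myo3a	6	1.01	0.02	6	4.33	1.57	0.02
intermediate_candidates	Foxo3	5	1.09	0.16	5	1.03	0.28	0.28
intermediate_candidates	Mitf	6	1.03	0.04	6	1.19	0.45	0.63
intermediate_candidates	Htt	5	1.03	0.02	5	1.20	0.54	0.84
intermediate_candidates	Thrb	5	1.00	0.00	5	1.22	0.44	0.28
intermediate_candidates	Foxo1	5	1.11	0.16	5	1.28	0.63	1
intermediate_candidates	Nr3c1	5	1.04	0.07	5	1.35	0.80	0.95
intermediate_candidates	Zic2	5	1.02	0.02	5	1.40	0.48	0.03
intermediate_candidates	Tnc	5	1.00	0.00	5	1.68	0.64	0.28
intermediate_candidates	Pou4f3	5	1.01	0.01	5	1.68	0.43	0.03
pulldown_targets	Gnb4	5	1.00	0.00	5	0.88	0.15	0.28
pulldown_targets	Tmem97	5	1.01	0.01	5	0.96	0.20	0.84
pulldown_targets	Sox5	5	1.03	0.04	5	0.98	0.08	0.95
pulldown_targets	Zfp251	5	1.04	0.04	5	0.99	0.38	0.28
pulldown_targets	Ablim	5	1.01	0.01	5	1.10	0.35	0.84
pulldown_targets	Clvs1	3	1.03	0.02	3	0.84	0.51	0.84
pulldown_targets	Mpv17l	5	1.01	0.01	5	1.25	0.50	0.84
pulldown_targets	Ankrd27	5	1.04	0.03	5	1.59	0.82	0.28
network_nodes	Fos	6	1.00	0.00	6	0.67	0.17	0.02
network_nodes	Ets1	6	1.03	0.03	6	0.95	0.25	0.84
network_nodes	Tgfb1	6	1.01	0.01	6	1.04	0.42	1
network_nodes	Sp1	6	1.00	0.00	6	1.11	0.18	0.63
network_nodes	Myc	6	1.02	0.03	6	1.12	0.36	1
network_nodes	Agt	6	1.04	0.02	6	1.22	0.34	0.63
network_nodes	Rhoa	6	1.01	0.01	6	1.23	0.50	1
network_nodes	Trp53	6	1.00	0.00	6	1.27	0.24	0.21
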