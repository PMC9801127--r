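id	index	label	element
tRNA-Leu-GAG-like	0	1	acceptor_stem
tRNA-Leu-GAG-like	1	2	acceptor_stem
tRNA-Leu-GAG-like	2	3	acceptor_stem
tRNA-Leu-GAG-like	3	4	acceptor_stem
tRNA-Leu-GAG-like	4	5	acceptor_stem
tRNA-Leu-GAG-like	5	6	acceptor_stem
tRNA-Leu-GAG-like	6	7	acceptor_stem
tRNA-Leu-GAG-like	7	8	d_arm
tRNA-Leu-GAG-like	8	9	d_arm
tRNA-Leu-GAG-like	9	10	d_arm
tRNA-Leu-GAG-like	10	11	d_arm
tRNA-Leu-GAG-like	11	12	d_arm
tRNA-Leu-GAG-like	12	13	d_arm
tRNA-Leu-GAG-like	13	14	d_arm
tRNA-Leu-GAG-like	14	15	d_arm
tRNA-Leu-GAG-like	15	16	d_arm
tRNA-Leu-GAG-like	16	17	d_arm
tRNA-Leu-GAG-like	17	18	d_arm
tRNA-Leu-GAG-like	18	19	d_arm
tRNA-Leu-GAG-like	19	20	d_arm
tRNA-Leu-GAG-like	20	20a	d_arm
tRNA-Leu-GAG-like	21	21	d_arm
tRNA-Leu-GAG-like	22	22	d_arm
tRNA-Leu-GAG-like	23	23	d_arm
tRNA-Leu-GAG-like	24	24	d_arm
tRNA-Leu-GAG-like	25	25	d_arm
tRNA-Leu-GAG-like	26	26	anticodon_arm
tRNA-Leu-GAG-like	27	27	anticodon_arm
tRNA-Leu-GAG-like	28	28	anticodon_arm
tRNA-Leu-GAG-like	29	29	anticodon_arm
tRNA-Leu-GAG-like	30	30	anticodon_arm
tRNA-Leu-GAG-like	31	31	anticodon_arm
tRNA-Leu-GAG-like	32	32	anticodon_arm
tRNA-Leu-GAG-like	33	33	anticodon_arm
tRNA-Leu-GAG-like	34	34	anticodon_arm
tRNA-Leu-GAG-like	35	35	anticodon_arm
tRNA-Leu-GAG-like	36	36	anticodon_arm
tRNA-Leu-GAG-like	37	37	anticodon_arm
tRNA-Leu-GAG-like	38	38	anticodon_arm
tRNA-Leu-GAG-like	39	39	anticodon_arm
tRNA-Leu-GAG-like	40	40	anticodon_arm
tRNA-Leu-GAG-like	41	41	anticodon_arm
tRNA-Leu-GAG-like	42	42	anticodon_arm
tRNA-Leu-GAG-like	43	43	anticodon_arm
tRNA-Leu-GAG-like	44	44	variable_region
tRNA-Leu-GAG-like	45	45	variable_region
tRNA-Leu-GAG-like	46	45a	variable_region
tRNA-Leu-GAG-like	47	45b	variable_region
tRNA-Leu-GAG-like	48	45c	variable_region
tRNA-Leu-GAG-like	49	45d	variable_region
tRNA-Leu-GAG-like	50	45e	variable_region
tRNA-Leu-GAG-like	51	45f	variable_region
tRNA-Leu-GAG-like	52	45g	variable_region
tRNA-Leu-GAG-like	53	45h	variable_region
tRNA-Leu-GAG-like	54	45i	variable_region
tRNA-Leu-GAG-like	55	45j	variable_region
tRNA-Leu-GAG-like	56	45k	variable_region
tRNA-Leu-GAG-like	57	46	variable_region
tRNA-Leu-GAG-like	58	47	variable_region
tRNA-Leu-GAG-like	59	48	variable_region
tRNA-Leu-GAG-like	60	49	t_arm
tRNA-Leu-GAG-like	61	50	t_arm
tRNA-Leu-GAG-like	62	51	t_arm
tRNA-Leu-GAG-like	63	52	t_arm
tRNA-Leu-GAG-like	64	53	t_arm
tRNA-Leu-GAG-like	65	54	t_arm
tRNA-Leu-GAG-like	66	55	t_arm
tRNA-Leu-GAG-like	67	56	t_arm
tRNA-Leu-GAG-like	68	57	t_arm
tRNA-Leu-GAG-like	69	58	t_arm
tRNA-Leu-GAG-like	70	59	t_arm
tRNA-Leu-GAG-like	71	60	t_arm
tRNA-Leu-GAG-like	72	61	t_arm
tRNA-Leu-GAG-like	73	62	t_arm
tRNA-Leu-GAG-like	74	63	t_arm
tRNA-Leu-GAG-like	75	64	t_arm
tRNA-Leu-GAG-like	76	65	t_arm
tRNA-Leu-GAG-like	77	66	acceptor_stem
tRNA-Leu-GAG-like	78	67	acceptor_stem
tRNA-Leu-GAG-like	79	68	acceptor_stem
tRNA-Leu-GAG-like	80	69	acceptor_stem
tRNA-Leu-GAG-like	81	70	acceptor_stem
tRNA-Leu-GAG-like	82	71	acceptor_stem
tRNA-Leu-GAG-like	83	72	acceptor_stem
tRNA-Leu-GAG-like	84	73	discriminator
tRNA-Leu-GAG-like	85	74	cca
tRNA-Leu-GAG-like	86	75	cca
tRNA-Leu-GAG-like	87	76	cca
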