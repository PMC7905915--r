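rs_id	control_major_hom	control_het	control_minor_hom	case_major_hom	case_het	case_minor_hom
rs700519	97	37	6	92	41	7
rs1048943	100	31	9	80	55	5
rs4646903	68	56	16	58	58	24
rs1056827	92	48	0	80	50	10
rs1056836	90	44	6	116	21	3
rs605059	47	73	20	46	69	25
rs4680	91	42	7	80	51	9
rs1042028	117	20	3	98	37	5
rs7439366	69	60	11	64	65	11
rs10822013	36	75	29	43	71	26
rs2981579	47	70	23	40	69	31
rs3784099	111	25	4	109	28	3
rs3803662	64	61	15	68	54	18
rs889312	42	67	31	35	66	39
rs981782	55	69	16	52	63	25
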