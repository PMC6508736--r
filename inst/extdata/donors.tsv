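sample_id	group	histology	age	weight_lbs	fsh_miu_ml	eggs_injected	embryos
C1	CS	Normal spermatogenesis	32	176	5.4	13	7
C2	CS	Normal spermatogenesis	55	278	8.9	4	1
C3	CS	Hypospermatogenesis	33	259	10.03	14	6
C4	CS	Hypospermatogenesis	31	181	No data	14	8
SCO5	SCO	Sertoli cell-only	30	185	15	13	9
SCO7	SCO	Sertoli cell-only	24	174	31.87	13	5
SCO8	SCO	Sertoli cell-only	34	155	15.2	20	16
SCO9	SCO	Sertoli cell-only	42	304	8.1	19	1
SCO10	SCO	Sertoli cell-only	35	248	22.42	8	1
SCO11	SCO	Sertoli cell-only	25	240	15.39	11	3
SCO12	SCO	Sertoli cell-only	36	136	29	8	6
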