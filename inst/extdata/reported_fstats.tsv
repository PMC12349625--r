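locus	Fis	Fit	Fst	Nm
Locus1	-0.185	0.191	0.317	0.537
Locus2	-0.387	-0.079	0.222	0.876
Locus3	-0.237	-0.054	0.148	1.435
Locus4	-0.275	0.040	0.247	0.762
Locus5	-0.365	-0.194	0.125	1.745
Locus6	-0.166	0.117	0.243	0.780
Locus7	-0.309	-0.044	0.202	0.987
Locus8	-0.294	0.033	0.253	0.740
Locus9	-0.294	0.009	0.235	0.816
Locus10	-0.129	0.109	0.211	0.936
Locus11	-0.237	0.132	0.298	0.589
Locus12	-0.269	-0.052	0.171	1.212
Locus13	-0.413	-0.147	0.188	1.079
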