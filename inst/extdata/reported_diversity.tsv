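population	N	Na	Ne	I	Ho	He	uHe	F
Pop1	3	3.769	3.226	1.214	0.615	0.667	0.800	0.104
Pop2	18	5.846	2.714	1.226	0.628	0.599	0.616	-0.054
Pop3	1	1.846	1.846	0.587	0.846	0.423	0.846	1.000
Pop4	6	4.923	3.671	1.398	0.744	0.707	0.772	-0.052
Pop5	5	4.231	3.189	1.234	0.769	0.646	0.718	-0.191
Pop6	1	1.692	1.692	0.480	0.692	0.346	0.692	1.000
Pop7	3	3.385	2.892	1.044	0.769	0.577	0.692	-0.338
Pop8	6	4.231	2.998	1.215	0.782	0.650	0.709	-0.206
Pop9	3	3.308	2.678	1.052	0.872	0.603	0.723	-0.447
Pop10	4	4.231	3.424	1.285	0.904	0.680	0.777	-0.341
Pop11	4	4.077	3.198	1.223	0.731	0.656	0.750	-0.131
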