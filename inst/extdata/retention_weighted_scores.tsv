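participant	age	sex	overall_error	temporal_precision	spatial_accuracy
1	54	F	0.702	-0.328	-0.534
2	64	F	0.084	0.116	0.201
3	72	F	0.123	-0.033	-0.141
4	67	F	-0.574	0.130	-0.342
5	60	F	-0.009	0.358	-0.422
6	51	M	-0.061	0.361	-0.206
7	63	M	-0.220	0.201	-0.268
8	68	M	-1.38	0.036	-0.899
9	80	F	-0.347	0.538	-0.676
10	69	M	-0.584	0.296	-0.655
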