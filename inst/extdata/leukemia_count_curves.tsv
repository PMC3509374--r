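tail	r	observed	null_q95
positive	0.1	2907	4128
positive	0.2	2058	2946
positive	0.3	1385	1985
positive	0.4	868	996
positive	0.5	514	325
positive	0.6	278	80
negative	0.1	2389	4245
negative	0.2	1628	2725
negative	0.3	1062	1785
negative	0.4	638	902
negative	0.5	379	372
negative	0.6	204	53
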