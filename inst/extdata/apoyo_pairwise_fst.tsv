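pair	fst_full	phi_full	fst_neutral	phi_neutral
zaliosus/globosus	0.223	0.353	0.141	0.219
zaliosus/astorquii	0.134	0.233	0.098	0.171
zaliosus/chancho	0.173	0.293	0.099	0.170
zaliosus/flaveolus	0.154	0.266	0.092	0.163
zaliosus/supercilius	0.188	0.317	0.119	0.207
globosus/astorquii	0.142	0.238	0.105	0.177
globosus/chancho	0.148	0.252	0.099	0.166
globosus/flaveolus	0.128	0.212	0.098	0.160
globosus/supercilius	0.159	0.263	0.112	0.184
astorquii/chancho	0.101	0.182	0.078	0.141
astorquii/flaveolus	0.062	0.114	0.049	0.092
astorquii/supercilius	0.084	0.153	0.064	0.118
chancho/flaveolus	0.105	0.188	0.071	0.129
chancho/supercilius	0.132	0.230	0.085	0.152
flaveolus/supercilius	0.052	0.096	0.036	0.067
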