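# Pairwise Kimura 2-parameter distances over the full ITS (ITS1-5.8S-ITS2)
# for 13 Dendrobium species (1-13) and the out-group Pholidota yunnanensis
# (14), printed to three decimals, lower triangle.
# Row format: <no> <name> <d to 1> <d to 2> ... <d to no-1>
1	Dendrobium_longicorna
2	Dendrobium_infundibulum	0.010
3	Dendrobium_trigonopus	0.128	0.123
4	Dendrobium_bellatulum	0.026	0.023	0.111
5	Dendrobium_williamsonii	0.050	0.047	0.116	0.037
6	Dendrobium_cariniferum	0.050	0.047	0.116	0.037	0.003
7	Dendrobium_sinense	0.020	0.016	0.135	0.032	0.052	0.052
8	Dendrobium_jenkinsii	0.136	0.132	0.150	0.122	0.132	0.136	0.136
9	Dendrobium_chrysotoxum	0.153	0.149	0.169	0.135	0.151	0.151	0.157	0.175
10	Dendrobium_thyrsiflorum	0.120	0.116	0.141	0.107	0.116	0.118	0.124	0.147	0.159
11	Dendrobium_densiflorum	0.118	0.114	0.139	0.105	0.114	0.116	0.122	0.143	0.157	0.007
12	Dendrobium_lindleyi	0.144	0.142	0.142	0.130	0.140	0.144	0.147	0.064	0.184	0.142	0.138
13	Dendrobium_sulcatum	0.124	0.122	0.146	0.111	0.120	0.122	0.126	0.149	0.157	0.098	0.096	0.154
14	Pholidota_yunnanensis	0.247	0.246	0.281	0.227	0.241	0.244	0.250	0.282	0.261	0.266	0.264	0.283	0.273
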