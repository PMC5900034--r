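metabolite	ppm_lo	ppm_hi
acetate	1.90	1.94
ascorbate	4.50	4.54
isovalerate	0.90	0.94
lactate	1.32	1.36
3-methyl-2-oxovalerate	1.08	1.12
butyrylglycine	0.91	0.95
butyrylglycine	1.60	1.64
cinnamoylglycine	6.71	6.75
hexanoylglycine	0.86	0.90
6H6MH3O	0.99	1.03
6H6MH3O	1.19	1.23
6H6MH3O	1.72	1.76
arabinose	4.51	4.55
D-xylose	4.57	4.61
D-xylose	5.19	5.23
D-glucose	4.64	4.68
D-glucuronate	4.63	4.67
fucose	1.23	1.27
2-oxoglutarate	2.43	2.47
2-oxoglutarate	2.99	3.03
citrate	2.54	2.58
citrate	2.68	2.72
succinate	2.39	2.43
1-methylnicotinamide	4.45	4.49
allantoin	5.38	5.42
dimethylamine	2.71	2.75
creatinine	3.02	3.06
creatinine	4.03	4.07
putrescine	1.76	1.80
taurine	3.25	3.29
taurine	3.41	3.45
trimethylamine	2.86	2.90
trimethylamine-N-oxide	3.25	3.29
trigonelline	4.42	4.46
ureidopropionate	2.36	2.40
ureidopropionate	3.29	3.33
hippurate	7.54	7.58
hippurate	7.62	7.66
hippurate	7.82	7.86
indoxylsulphate	7.49	7.53
indoxylsulphate	7.69	7.73
4-cresol-glucuronide	2.28	2.32
4-cresol-glucuronide	5.06	5.10
4-cresol-sulphate	2.33	2.37
phenylacetylglycine	7.35	7.39
phenylacetylglycine	7.41	7.45
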