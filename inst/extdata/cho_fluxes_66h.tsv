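# Observed specific uptake fluxes from a CHO cell batch cultivation,
# 66 h post inoculation (mid-exponential, pseudo steady state).
# flux in nmol/1e6 cells/h, consumption positive, production negative;
# cv in percent (sd of flux divided by |flux|).
name	flux	cv
Acetate	-1.03	5.08
Alanine	-33.95	3.32
Ammonia	-17.65	23.10
Arginine	2.52	16.33
Asparagine	2.21	7.64
Aspartate	2.14	7.09
Carbohydrates	-2.13	12.25
Citrate	-1.56	7.14
Cystine	0.33	19.04
DNA	-0.31	13.15
Formate	-7.52	2.06
Glucose	161.87	2.89
Glutamate	-0.17	213.18
Glutamax	17.98	10.69
Glutamine	7.35	12.48
Glycine	-2.25	8.79
Histidine	1.02	14.92
Isoleucine	1.52	8.13
Lactate	-283.53	3.19
Leucine	2.66	9.47
Lipids	-1.36	14.86
Lysine	1.80	8.05
Malate	-0.40	13.78
Methionine	0.89	6.44
Phenylalanine	1.19	7.04
Proline	1.94	9.17
Protein	-32.69	13.11
Pyroglutamate	-3.86	3.86
Pyruvate	-2.62	5.74
RNA	-0.89	13.77
Serine	2.64	12.36
Succinate	-0.15	15.52
Threonine	1.70	11.45
Tryptophan	0.34	17.40
Tyrosine	1.11	6.57
Valine	2.24	5.26
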