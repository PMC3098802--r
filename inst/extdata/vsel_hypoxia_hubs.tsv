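name	gene	degree	q
FBJ osteosarcoma oncogene	Fos	42	0.019
Peroxisome proliferator activated receptor gamma	Pparg	39	0.039
Epidermal growth factor receptor	Egfr	28	0.00053
Early growth response 1	Egr1	19	0.0069
Early growth response 2	Egr2	19	0.028
Integrin beta 3	Itgb3	18	0.0033
TATA box binding protein	Tbp	15	0.022
Hypoxia-inducible factor 2 alpha	Hif2a	15	0.017
Collagen type I alpha 1	Col1a1	15	0.025
Heat shock protein 8	Hspa8	14	0.041
Insulin receptor substrate 1	Irs1	13	0.000089
Insulin-like growth factor binding protein 5	Igfbp5	12	0.00000057
Heat shock protein 5	Hspa5	11	0.025
Disrupted in schizophrenia 1	Disc1	11	0.0081
Homeobox A9	Hoxa9	11	0.018
Von Willebrand factor homolog	Vwf	11	0.0091
Peroxisome proliferative activated receptor gamma coactivator 1 alpha	Ppargc1a	10	0.00021
Hypermethylated in cancer 1	Hic1	10	0.026
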