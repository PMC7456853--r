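mirna	mirna_fc	protein	protein_fc
let-7	0.39	Non-specific lipid-transfer protein	1.54
let-7	0.39	Prefoldin subunit 2	1.46
miR-2b	0.41	Calmodulin	1.45
miR-2b	0.41	Cathepsin F	1.28
miR-2b	0.41	Eukaryotic translation initiation factor 5A	1.32
miR-98	0.39	Non-specific lipid-transfer protein	1.54
miR-98	0.39	Prefoldin subunit 2	1.46
miR-219-1-3p	0.43	Calcium-regulated heat stable protein 1	1.42
miR-219-1-3p	0.43	Cyclin B	1.28
miR-219-1-3p	0.43	Non-specific lipid-transfer protein	1.54
miR-219-1-3p	0.43	Sorting nexin-12	1.70
miR-219-1-3p	0.43	Triosephosphate isomerase	1.34
miR-219b-3p	0.40	Cyclin B	1.28
miR-219b-3p	0.40	Masquerade-like protein	1.22
miR-219b-3p	0.40	Sorting nexin-12	1.70
miR-263a	0.47	Farnesoic acid O-methyltransferase	1.67
miR-317	0.21	Calmodulin	1.45
miR-466b-3p	0.41	Calmodulin	1.45
miR-466b-3p	0.41	Cathepsin F	1.28
miR-466b-3p	0.41	Insulin receptor	1.58
miR-466b-3p	0.41	Masquerade-like protein	1.22
miR-466b-3p	0.41	Sorting nexin-12	1.70
miR-466b-3p	0.41	Triosephosphate isomerase	1.34
miR-3907	0.49	AMP-activated protein kinase alpha subunit	1.60
miR-4171	0.39	Farnesoic acid O-methyltransferase	1.67
novel-5	2.69	Cathepsin D	0.79
novel-61	0.29	Aspartylglucosaminidase	1.67
novel-61	0.29	Calmodulin	1.45
novel-65	2.80	Peroxiredoxin 1	0.78
novel-68	0.34	Cyclin B	1.28
novel-72	0.37	60S acidic ribosomal protein P2	1.39
novel-72	0.37	Calcium-regulated heat stable protein 1	1.42
novel-72	0.37	Cathepsin F	1.28
novel-72	0.37	Prefoldin	1.84
novel-75	0.47	Cathepsin F	1.28
novel-75	0.47	DnaJ homolog subfamily B member 9 precursor	1.32
novel-75	0.47	Insulin receptor	1.58
novel-75	0.47	RAE1 RNA export 1 homolog	1.33
novel-77	0.38	AMP-activated protein kinase alpha subunit	1.60
novel-77	0.38	Cyclin B	1.28
novel-77	0.38	Eukaryotic translation initiation factor 5A	1.32
novel-77	0.38	Phosphopyruvate hydratase	1.32
novel-77	0.38	Prefoldin	1.84
novel-85	0.21	Calnexin	1.40
novel-85	0.21	Cyclin B	1.28
novel-85	0.21	Program cell death 5-like	1.66
novel-96	0.44	60S acidic ribosomal protein P2	1.39
novel-96	0.44	AMP-activated protein kinase alpha subunit	1.60
novel-96	0.44	Calnexin	1.40
novel-96	0.44	Cytochrome c	1.67
novel-96	0.44	Peroxiredoxin 6	1.61
novel-96	0.44	Phosphopyruvate hydratase	1.32
novel-96	0.44	Calmodulin	1.45
novel-100	0.44	Program cell death 5-like	1.66
novel-112	0.32	Aspartylglucosaminidase	1.67
novel-112	0.32	Similar to adaptin ear-binding coat-associated protein 2	1.25
novel-134	3.45	Ribosomal protein S26	0.78
novel-136	0.46	AMP-activated protein kinase alpha subunit	1.60
novel-136	0.46	Eukaryotic translation initiation factor 5A	1.32
novel-136	0.46	Non-specific lipid-transfer protein	1.54
novel-136	0.46	Triosephosphate isomerase	1.34
novel-142	0.44	Calcium-regulated heat stable protein 1	1.42
novel-142	0.44	Calnexin	1.40
novel-142	0.44	Triosephosphate isomerase	1.34
novel-154	0.08	Aspartylglucosaminidase	1.67
novel-167	0.47	AMP-activated protein kinase alpha subunit	1.60
novel-167	0.47	Peroxiredoxin 2	1.32
novel-167	0.47	Phosphopyruvate hydratase	1.32
novel-167	0.47	Protein-L-isoaspartate O-methyltransferase	1.48
novel-167	0.47	Thymosin beta	1.55
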