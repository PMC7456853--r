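accession	name	fold_change
XP_003702718.1	Peritrophin-1-like	3.66
XP_012151113.1	Fibrillin-2-like isoform X2	3.08
AAY56093.1	Death-associated protein-like	2.32
ACZ02405.1	Heat shock protein 70	2.28
XP_003248548.1	Clathrin light chain-like	1.95
XP_002431005.1	Ubiquitin-fold modifier 1 precursor	1.90
XP_002404909.1	Prefoldin	1.84
AFE88627.1	Thioredoxin 2	1.79
KDR08860.1	Tumor protein D54	1.79
XP_004922887.1	BolA-like protein	1.76
XP_012176731.1	Fibril-forming collagen alpha chain like	1.76
XP_974307.1	Similar to par-6 gamma	1.74
ADZ96217.1	JHE-like carboxylesterase 1	1.70
EFN74540.1	Sorting nexin-12	1.70
AFS60116.1	Selenoprotein M	1.69
NP_001037686.1	Aspartylglucosaminidase	1.67
BAJ22990.1	Cytochrome c	1.67
ACL26692.1	Farnesoic acid O-methyltransferase	1.67
XP_001865898.1	Antioxidant enzyme	1.66
AAY57406.1	Program cell death 5-like	1.66
ACU82846.1	Acyl-CoA-binding protein	1.64
ACO11851.1	RNA-binding protein 1	1.64
AAO73307.1	Ovary development-related protein	1.63
ACO11926.1	Charged multivesicular body protein 5	1.61
ACJ53746.1	Peroxiredoxin 6	1.61
XP_001942794.1	39S ribosomal protein L12, mitochondrial-like isoform 1	1.60
ACL13568.1	AMP-activated protein kinase alpha subunit	1.60
ACY66390.1	FK506-binding protein 1A	1.60
ABI98678.1	Ubiquitin-conjugating enzyme	1.59
XP_972770.2	Insulin receptor	1.58
ADE60733.1	Myosin essential light chain	1.57
NP_001103783.1	Tropomyosin-2 isoform 3	1.57
ABF55966.2	Cleavage stimulation factor 64-kDa subunit	1.56
EFN66390.1	PERQ amino acid-rich with GYF domain-containing protein 2	1.56
XP_796085.2	Transcription and mRNA export factor ENY2	1.56
XP_011300302.1	Prefoldin subunit 1	1.55
KDR23647.1	Protein phosphatase inhibitor 2	1.55
ACR56783.1	Small ubiquitin-like modifier-1	1.55
ACY66642.1	Thymosin beta	1.55
EGI57685.1	Non-specific lipid-transfer protein	1.54
KDR12501.1	Spondin-1	1.54
EFN86015.1	GS1-like protein	1.53
XP_003723328.1	ES1 protein homolog, mitochondrial-like	1.52
XP_011501070.1	Far upstream element-binding protein 1 isoform X3	1.52
XP_003445744.1	Methylmalonyl-CoA epimerase	1.52
EGW07359.1	Peptidyl-prolyl cis-trans isomerase, mitochondrial	1.52
XP_008470922.1	Verprolin-like	1.52
XP_003451145.1	Aminopeptidase W07G4.4-like	1.51
XP_012259502.1	DnaJ homolog subfamily B member 11	1.51
XP_001847373.1	Ubiquinol-cytochrome c reductase complex 14 kDa protein	1.51
ADW24146.1	Vesicle-associated membrane protein-associated protein	1.5
AAX94762.1	Vitellogenin	1.5
XP_003707900.1	28S ribosomal protein S36, mitochondrial-like	1.49
XP_002427853.1	Protein-L-isoaspartate O-methyltransferase	1.48
BAM18170.1	Prefoldin subunit	1.47
AGF39576.1	Double WAP domain-containing protein	1.46
XP_002413321.1	LIM domain-binding protein	1.46
XP_001660469.1	Low-density lipoprotein receptor	1.46
EGI66356.1	Prefoldin subunit 2	1.46
ELW71144.1	Calmodulin	1.45
KDR23803.1	Outer dense fiber protein 3	1.45
XP_001947263.2	Upstream activation factor subunit spp27-like	1.45
XP_008473520.1	Pumilio homolog 1-like	1.44
NP_001090127.1	Tubulin folding cofactor B	1.44
ACO36738.1	Ubiquitin carboxyl-terminal esterase L3	1.43
KMQ90936.1	Barrier-to-autointegration factor	1.42
NP_001156264.1	Calcium-regulated heat stable protein 1	1.42
XP_002423140.1	Charged multivesicular body protein 4C	1.42
XP_003690694.1	Synaptosomal-associated protein 29-like	1.42
ACI13851.1	Extracellular copper-zinc superoxide dismutase	1.41
XP_002425615.1	Methionyl-tRNA synthetase	1.41
XP_008199673.1	Nuclear protein MDM1 isoform X4	1.41
XP_003486756.1	Stress-induced-phosphoprotein 1-like isoform 1	1.41
ETN61219.1	Aldehyde oxidase	1.40
ADO00931.1	Calnexin	1.40
XP_002413938.1	Low-density lipoprotein receptor	1.40
KDR20387.1	Phosphoglycerate mutase 2	1.40
ACY66501.1	60S acidic ribosomal protein P2	1.39
XP_004065994.1	Cytosol aminopeptidase-like	1.39
XP_011416416.1	Histidine triad nucleotide-binding protein 2	1.39
EKC27215.1	Ras GTPase-activating protein-binding protein 2	1.39
EKC33829.1	Methenyltetrahydrofolate synthetase domain-containing protein	1.38
XP_011157802.1	Short-chain specific acyl-CoA dehydrogenase	1.38
XP_012150508.1	Multiple coagulation factor deficiency protein 2 homolog	1.37
XP_002409815.1	PDZ domain-containing protein	1.37
XP_001943654.1	Bifunctional methylenetetrahydrofolate dehydrogenase/cyclohydrolase	1.36
NP_001164152.1	Held out wings	1.36
ACR54112.1	Ribosomal protein P1	1.36
KDR12892.1	Syntaxin-12	1.36
XP_003400244.1	Cyclin-dependent kinase 6-like	1.35
XP_005175277.1	ATP synthase subunit d	1.34
ACH88358.1	Cell division cycle 2	1.34
ADN52396.1	Triosephosphate isomerase	1.34
EFA07536.1	RAE1 RNA export 1 homolog	1.33
ACO14747.1	Calponin-3	1.32
NP_001020355.1	DnaJ homolog subfamily B member 9 precursor	1.32
ACZ06791.1	Eukaryotic translation initiation factor 5A	1.32
AET36895.1	Peroxiredoxin 2	1.32
AAC78141.1	Phosphopyruvate hydratase	1.32
AFC17961.1	O-methyltransferase	1.31
XP_002415663.1	Alternative splicing factor ASF/SF2	1.30
EKC42097.1	Cathepsin F	1.28
ACI46952.1	Cyclin B	1.28
KDR07772.1	Plastin-2	1.28
XP_012267954.1	Golgi resident protein GCP60	1.27
XP_972648.1	Similar to adaptin ear-binding coat-associated protein 2	1.25
ACY66506.1	Ubiquitin associated protein 2-like protein	1.25
KFM60612.1	DnaJ-like protein subfamily A member 2	1.24
XP_003705474.1	Aconitate hydratase	1.23
ADQ55791.1	Antimicrobial peptide hyastatin	1.23
CAA72032.2	Masquerade-like protein	1.22
XP_973346.1	Phosphoacetylglucosamine mutase	0.83
AAC64660.1	Pacifastin heavy chain precursor	0.82
AEF32710.1	Translationally controlled tumor protein	0.81
ACY66537.1	60S ribosomal protein L27	0.80
AAZ22828.1	Lymphoid organ expressed yellow head virus receptor protein	0.80
KFM60603.1	60S ribosomal protein L7a	0.79
ABQ10738.1	Cathepsin D	0.79
XP_011136175.1	Proteasome subunit alpha type-5	0.79
XP_972566.1	Succinate semialdehyde dehydrogenase, mitochondrial	0.79
AET34923.1	Peroxiredoxin 1	0.78
XP_002401133.1	Ribosomal protein S26	0.78
NP_001037263.1	Ribosomal protein S8	0.77
XP_003705948.1	1,2-dihydroxy-3-keto-5-methylthiopentene dioxygenase-like	0.75
XP_002423307.1	cAMP-dependent protein kinase catalytic subunit	0.73
ACN87221.1	Phenoloxidase activating factor	0.72
XP_007442568.1	Glutathione peroxidase 7-like	0.71
KFM75426.1	Protein canopy-like protein	0.71
ABX71209.1	Glycosyl-phosphatidylinositol-linked carbonic anhydrase	0.69
AAW57889.1	Hemocyanin subunit 1	0.69
AAW57890.1	Hemocyanin subunit 2	0.69
AAW57891.1	Hemocyanin subunit 3	0.65
AAA96966.2	Hemocyanin subunit 6	0.59
AAF64305.1	Hemocyanin subunit	0.56
EGI63299.1	Histone-lysine N-methyltransferase trr	0.24
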