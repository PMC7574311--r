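accession	sample	coverage_pct	n_peptides	n_spectra
60S_ribosomal_protein_L11	bait	49.72	6	11
Arginine_biosynthesis_bifunctional_protein	bait	26.72	7	21
Beta-xylosidase_alpha-L-arabinofuranosidase	bait	25.32	15	30
Chalcone_synthase_2	bait	31.62	9	38
Chalcone_synthase_4	bait	28.53	8	34
Dihydroflavonol_4-reductase	bait	33.18	6	12
Glutamate_synthase_NADH_amyloplastic	bait	19.51	30	99
Glycogen_synthase_kinase-3_homolog-3	bait	37.23	11	27
Methylthioribose-1-phosphate_isomerase	bait	38.14	11	15
Phenylalanine_ammonia-lyase	bait	21.38	12	21
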