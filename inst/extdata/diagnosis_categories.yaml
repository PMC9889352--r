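# Diagnosis categories for the packaged representative lexicon.
# exclusive_group: mutually exclusive severity tier; group_rank: 1 = malignant
# (highest severity) ... 4 = benign.  This is a synthetic stand-in dictionary
# built for the bundled corpus generator and examples, not an institutional
# dictionary; a site-specific table can be dropped in via load_lexicon().
- category_id: adenocarcinoma
  display_name: Adenocarcinoma
  exclusive_group: malignant
  group_rank: 1
- category_id: squamous_cell_carcinoma
  display_name: Squamous cell carcinoma
  exclusive_group: malignant
  group_rank: 1
- category_id: small_cell_carcinoma
  display_name: Small cell carcinoma
  exclusive_group: malignant
  group_rank: 1
- category_id: non_small_cell_carcinoma
  display_name: Non-small cell carcinoma
  exclusive_group: malignant
  group_rank: 1
- category_id: carcinoma_nos
  display_name: Carcinoma, not otherwise specified
  exclusive_group: malignant
  group_rank: 1
- category_id: large_cell_neuroendocrine_carcinoma
  display_name: Large cell neuroendocrine carcinoma
  exclusive_group: malignant
  group_rank: 1
- category_id: metastasis
  display_name: Metastasis
  exclusive_group: malignant
  group_rank: 1
- category_id: lymphoma
  display_name: Lymphoma
  exclusive_group: malignant
  group_rank: 1
- category_id: melanoma
  display_name: Melanoma
  exclusive_group: malignant
  group_rank: 1
- category_id: malignant_nos
  display_name: Malignant, not further specified
  exclusive_group: malignant
  group_rank: 1
- category_id: suspicious_malignancy
  display_name: Suspicious for malignancy
  exclusive_group: suspicious
  group_rank: 2
- category_id: atypical_cells
  display_name: Atypical cells
  exclusive_group: suspicious
  group_rank: 2
- category_id: insufficient
  display_name: Insufficient for diagnosis
  exclusive_group: insufficient
  group_rank: 3
- category_id: nondiagnostic
  display_name: Non-diagnostic / unsatisfactory
  exclusive_group: insufficient
  group_rank: 3
- category_id: benign_lymphocytes
  display_name: Benign lymphocytes
  exclusive_group: benign
  group_rank: 4
- category_id: reactive_lymphoid_hyperplasia
  display_name: Reactive lymphoid hyperplasia
  exclusive_group: benign
  group_rank: 4
- category_id: granulomatous_inflammation
  display_name: Granulomatous inflammation
  exclusive_group: benign
  group_rank: 4
- category_id: negative_for_malignancy
  display_name: Negative for malignancy
  exclusive_group: benign
  group_rank: 4
- category_id: normal_lymph_node
  display_name: Normal lymph node
  exclusive_group: benign
  group_rank: 4
- category_id: anthracotic_pigment
  display_name: Anthracotic pigment
  exclusive_group: benign
  group_rank: 4
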