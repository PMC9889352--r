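phrase	category_id
adenocarcinoma	adenocarcinoma
metastatic adenocarcinoma	adenocarcinoma
adenocarcinoma of pulmonary origin	adenocarcinoma
non-small cell carcinoma favor adenocarcinoma	adenocarcinoma
non-small cell carcinoma consistent with adenocarcinoma	adenocarcinoma
squamous cell carcinoma	squamous_cell_carcinoma
squamous carcinoma	squamous_cell_carcinoma
metastatic squamous cell carcinoma	squamous_cell_carcinoma
keratinizing squamous cell carcinoma	squamous_cell_carcinoma
non-small cell carcinoma favor squamous cell carcinoma	squamous_cell_carcinoma
small cell carcinoma	small_cell_carcinoma
small cell lung carcinoma	small_cell_carcinoma
small cell neuroendocrine carcinoma	small_cell_carcinoma
consistent with small cell carcinoma	small_cell_carcinoma
non-small cell carcinoma	non_small_cell_carcinoma
non-small cell lung carcinoma	non_small_cell_carcinoma
non-small cell carcinoma not otherwise specified	non_small_cell_carcinoma
carcinoma not otherwise specified	carcinoma_nos
poorly differentiated carcinoma	carcinoma_nos
carcinoma	carcinoma_nos
large cell neuroendocrine carcinoma	large_cell_neuroendocrine_carcinoma
metastatic carcinoma	metastasis
metastasis	metastasis
metastatic malignancy	metastasis
metastatic tumor	metastasis
lymphoma	lymphoma
non-hodgkin lymphoma	lymphoma
hodgkin lymphoma	lymphoma
lymphoproliferative disorder	lymphoma
metastatic melanoma	melanoma
melanoma	melanoma
malignant cells present	malignant_nos
malignant cells identified	malignant_nos
positive for malignancy	malignant_nos
positive for malignant cells	malignant_nos
malignant not further specified	malignant_nos
malignant neoplasm	malignant_nos
malignant cells	malignant_nos
malignant	malignant_nos
suspicious for malignancy	suspicious_malignancy
suspicious for malignant cells	suspicious_malignancy
suspicious for carcinoma	suspicious_malignancy
suspicious for metastatic carcinoma	suspicious_malignancy
atypical cells present	atypical_cells
atypical lymphoid cells	atypical_cells
rare atypical cells	atypical_cells
atypical cells	atypical_cells
insufficient for diagnosis	insufficient
insufficient cellularity	insufficient
insufficient material	insufficient
scant cellularity	insufficient
inadequate specimen	insufficient
inadequate for evaluation	insufficient
non-diagnostic	nondiagnostic
nondiagnostic	nondiagnostic
unsatisfactory for evaluation	nondiagnostic
unsatisfactory specimen	nondiagnostic
acellular specimen	nondiagnostic
benign lymphocytes	benign_lymphocytes
benign-appearing lymphocytes	benign_lymphocytes
polymorphous lymphocytes	benign_lymphocytes
mature lymphocytes	benign_lymphocytes
benign lymphoid population	benign_lymphocytes
reactive lymphoid hyperplasia	reactive_lymphoid_hyperplasia
reactive lymphocytes	reactive_lymphoid_hyperplasia
reactive lymphoid cells	reactive_lymphoid_hyperplasia
follicular hyperplasia	reactive_lymphoid_hyperplasia
granulomatous inflammation	granulomatous_inflammation
non-necrotizing granulomas	granulomatous_inflammation
necrotizing granulomas	granulomatous_inflammation
granulomas present	granulomatous_inflammation
granuloma	granulomatous_inflammation
epithelioid histiocytes	granulomatous_inflammation
negative for malignant cells	negative_for_malignancy
negative for malignancy	negative_for_malignancy
no malignant cells identified	negative_for_malignancy
no malignant cells	negative_for_malignancy
no evidence of malignancy	negative_for_malignancy
normal lymph node	normal_lymph_node
unremarkable lymphoid tissue	normal_lymph_node
anthracotic pigment	anthracotic_pigment
anthracosis	anthracotic_pigment
pigmented macrophages	anthracotic_pigment
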