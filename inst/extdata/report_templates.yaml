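# Versioned template bank for the synthetic report generator.
# Placeholders: {modality} (EBUS/EUS), {site} (a station synonym drawn from
# the site lexicon), {phrase} (a diagnosis phrase of the record's true
# category).  Distractor sentences are appended after the diagnosis phrase so
# that severity-then-offset tie-breaking preserves the true category; the
# heavy distractors deliberately embed lexicon phrases of equal-or-lower
# severity (negations, background descriptions) to stress the matcher.
version: 1
source_templates:
  - "{modality}-guided fine needle aspiration, lymph node, {site}."
  - "{modality} FNA, lymph node, {site}."
  - "Lymph node, {site}; {modality}-guided aspirate."
  - "{modality} needle aspiration, mediastinal lymph node, {site}."
diagnosis_templates:
  - "{phrase}."
  - "FINDINGS: {phrase}."
  - "{phrase}. See comment."
  - "Cytologic interpretation: {phrase}."
mild_distractors:
  - "Correlation with clinical and radiologic findings is recommended."
  - "Cell block examined."
  - "Immunostains reviewed; results incorporated above."
  - "Adequacy assessed at the time of procedure."
heavy_distractors:
  benign:
    - "Negative for malignant cells."
    - "No granulomas identified."
  suspicious:
    - "No granulomas identified."
    - "Scattered mature lymphocytes in the background."
  malignant:
    - "Atypical cells present in a necrotic background."
    - "Rare mature lymphocytes in the background."
  insufficient:
    - "Rare benign lymphocytes only."
    - "Blood and mucus only."
  unclassified: []
unclassified_texts:
  - "Material reviewed with the clinical team; interpretation deferred."
  - "Report issued separately; refer to the surgical specimen."
  - "Descriptive findings only; no further characterization possible."
consult_templates:
  - "CONSULTATION: Reviewed; concur with {phrase}."
addendum_templates:
  - "ADDENDUM: Immunohistochemical stains support {phrase}."
  - "Addendum: additional material shows {phrase}."
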