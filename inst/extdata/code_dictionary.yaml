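# Representative, editable code dictionary for the synthetic-claims pipeline.
# The groups carry the codes named in the main derivation rules (CPT 33249
# primary implant, 33225 concurrent CRT pacing lead, ICD-9-CM 996.61 device
# infection, and the CIED monitoring CPT codes); the remaining groups are
# representative stand-ins for unpublished supplementary lists and can be
# replaced by users who hold the authoritative sets.
procedures:
  primary_implant: ["33249"]
  crtd_pacing_lead: ["33225"]
  generator_change: ["33262", "33263", "33264"]
  lead_revision: ["33215", "33218", "33220", "33226"]
  generator_removal: ["33233", "33241"]
  pocket_revision: ["33222", "33223"]
  maintenance: ["93289", "93282", "93283", "93284", "93295", "93296", "93287"]
diagnoses:
  device_infection: ["996.61"]
  infection_related: ["038.9", "790.7", "421.0", "682.9", "780.61"]
  complication: ["423.3", "512.1", "427.5", "415.11", "998.12"]
charlson:
  - {code: "410", condition: myocardial_infarction, weight: 1}
  - {code: "412", condition: myocardial_infarction, weight: 1}
  - {code: "428", condition: congestive_heart_failure, weight: 1}
  - {code: "443.9", condition: peripheral_vascular_disease, weight: 1}
  - {code: "434", condition: cerebrovascular_disease, weight: 1}
  - {code: "436", condition: cerebrovascular_disease, weight: 1}
  - {code: "290", condition: dementia, weight: 1}
  - {code: "496", condition: chronic_pulmonary_disease, weight: 1}
  - {code: "491", condition: chronic_pulmonary_disease, weight: 1}
  - {code: "714.0", condition: rheumatic_disease, weight: 1}
  - {code: "533", condition: peptic_ulcer_disease, weight: 1}
  - {code: "571.5", condition: mild_liver_disease, weight: 1}
  - {code: "250.0", condition: diabetes, weight: 1}
  - {code: "250.4", condition: diabetes_with_complications, weight: 2}
  - {code: "342", condition: hemiplegia, weight: 2}
  - {code: "585", condition: renal_disease, weight: 2}
  - {code: "162", condition: malignancy, weight: 2}
  - {code: "174", condition: malignancy, weight: 2}
  - {code: "185", condition: malignancy, weight: 2}
  - {code: "572.2", condition: moderate_severe_liver_disease, weight: 3}
  - {code: "197", condition: metastatic_solid_tumor, weight: 6}
  - {code: "198", condition: metastatic_solid_tumor, weight: 6}
  - {code: "042", condition: aids_hiv, weight: 6}
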