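# Default code dictionary for the antibiotic-disability pipeline.
#
# Indication code families are the literal ICD-9 codes used to define the
# three uncomplicated infections; every other code is a synthetic stand-in
# (this file is the injection point for a real ICD-9 -> SNOMED -> MedDRA
# mapping when licensed vocabularies are available).
indications:
  bronchitis: ["466.0"]
  sinusitis: ["461.0", "461.1", "461.2", "461.3", "461.8", "461.9"]
  uti: ["599.0"]

# Oral antibiotic dispensing codes by arm. FQ is the target arm; the
# comparator arm is azithromycin (sinusitis/bronchitis) or
# sulfamethoxazole/trimethoprim (UTI).
exposures:
  fq:
    - ciprofloxacin
    - levofloxacin
    - moxifloxacin
    - ofloxacin
    - gemifloxacin
    - gatifloxacin
    - norfloxacin
  az: [azithromycin]
  st: [smx_tmp]

# Six collapsed adverse-event categories spanning seven MedDRA system organ
# classes: "sensory" absorbs both ear/labyrinth and eye disorder codes.
soc_map:
  peripheral_nervous: [AE_PNS_01, AE_PNS_02, AE_PNS_03]
  neuropsychiatric: [AE_NPS_01, AE_NPS_02, AE_NPS_03]
  musculoskeletal: [AE_MSK_01, AE_MSK_02, AE_MSK_03]
  sensory: [AE_EAR_01, AE_EAR_02, AE_EYE_01, AE_EYE_02]
  cardiovascular: [AE_CVD_01, AE_CVD_02, AE_CVD_03]
  skin: [AE_SKN_01, AE_SKN_02, AE_SKN_03]

exclusions:
  # conditions excluding entry when seen in the 183-day lookback
  general_conditions:
    - EXCL_FIBROMYALGIA
    - EXCL_RHEUMATOID_ARTHRITIS
    - EXCL_LUPUS
    - EXCL_DIABETES_COMPLICATED
    - EXCL_LYME
    - EXCL_MULTIPLE_SCLEROSIS
    - EXCL_RENAL_IMPAIRMENT
    - EXCL_HEPATIC_IMPAIRMENT
    - EXCL_HIV
    - EXCL_JOINT_REPLACEMENT
    - EXCL_ORGAN_TRANSPLANT
  # long-term oral steroids: cumulative days supplied >= 30 in the lookback
  steroid_drugs: [oral_steroid]
  steroid_min_days: 30
  # any dispensing in the lookback excludes
  chemotherapy_drugs: [chemotherapy]
  # indication-specific exclusions in the 92-day lookback; "inpatient" lists
  # apply only to hospital diagnoses, "any_setting" to either setting
  condition_specific:
    bronchitis:
      inpatient: ["466.0", EXCL_PNEUMONIA, EXCL_HYPOXEMIA, EXCL_RESP_INSUFFICIENCY]
      any_setting: [EXCL_PNEUMONIA, EXCL_HYPOXEMIA, EXCL_RESP_INSUFFICIENCY]
    sinusitis:
      inpatient: ["461.0", "461.1", "461.2", "461.3", "461.8", "461.9", EXCL_SINUS_SURGERY]
      any_setting: [EXCL_SINUS_SURGERY, EXCL_SINUS_PROCEDURE]
    uti:
      inpatient: ["599.0"]
      any_setting:
        - EXCL_URINARY_CATHETER
        - EXCL_URINARY_OBSTRUCTION
        - EXCL_PYELONEPHRITIS
        - EXCL_RENAL_ABSCESS
        - EXCL_URINARY_MALFORMATION
        - EXCL_CHRONIC_RENAL_FAILURE

# 45 outcome conditions assumed causally unrelated to either arm; synthetic
# placeholders for the study's supplementary control list.
negative_controls:
  - NC_01
  - NC_02
  - NC_03
  - NC_04
  - NC_05
  - NC_06
  - NC_07
  - NC_08
  - NC_09
  - NC_10
  - NC_11
  - NC_12
  - NC_13
  - NC_14
  - NC_15
  - NC_16
  - NC_17
  - NC_18
  - NC_19
  - NC_20
  - NC_21
  - NC_22
  - NC_23
  - NC_24
  - NC_25
  - NC_26
  - NC_27
  - NC_28
  - NC_29
  - NC_30
  - NC_31
  - NC_32
  - NC_33
  - NC_34
  - NC_35
  - NC_36
  - NC_37
  - NC_38
  - NC_39
  - NC_40
  - NC_41
  - NC_42
  - NC_43
  - NC_44
  - NC_45
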