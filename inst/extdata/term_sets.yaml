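# Placeholder (synthetic) preferred-term sets.
#
# Real regulatory dictionaries are licensed, so the PTs below are synthetic
# stand-ins with the same structure as the real event definitions: a 3-term
# set for hemorrhagic transformation (ht), a 9-term set for intracerebral
# hemorrhage (ich), and narrow comorbidity sets used by the predictor module.
# Replace these lists with licensed PT / SMQ-narrow lists for production use;
# every analysis function takes term sets as a parameter.
ht:
  - haemorrhagic transformation placeholder 1
  - haemorrhagic transformation placeholder 2
  - haemorrhagic transformation placeholder 3
ich:
  - intracerebral haemorrhage placeholder 1
  - intracerebral haemorrhage placeholder 2
  - intracerebral haemorrhage placeholder 3
  - intracerebral haemorrhage placeholder 4
  - intracerebral haemorrhage placeholder 5
  - intracerebral haemorrhage placeholder 6
  - intracerebral haemorrhage placeholder 7
  - intracerebral haemorrhage placeholder 8
  - intracerebral haemorrhage placeholder 9
hypertension:
  - hypertension placeholder 1
  - hypertension placeholder 2
diabetes_mellitus:
  - diabetes mellitus placeholder 1
  - diabetes mellitus placeholder 2
heart_failure:
  - cardiac failure placeholder 1
  - cardiac failure placeholder 2
convulsive_disorder:
  - convulsion placeholder 1
chronic_kidney_disease:
  - chronic kidney disease placeholder 1
acute_myocardial_infarction:
  - acute myocardial infarction placeholder 1
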