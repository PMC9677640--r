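# Bundled default codebooks.
#
# The cough section reproduces the published diagnostic cough codebook:
# each row is an (ICD-10 code, standard disease name) pair mapped to a
# cough category. Standard disease names are the Japanese-vernacular
# labels that disambiguate subtypes sharing one ICD-10 code (notably the
# R05 variants); they are carried here as romanised opaque keys and
# matching is exact-string on the (icd10, standard_name) pair.
#
# The disease and medication sections are SYNTHETIC stand-ins: the exact
# code lists used in the source database are not public, so these use
# plausible ICD-10 chapter prefixes and representative ATC leaves. They
# are matched by longest code prefix. Replace them with a site-specific
# codebook for use on real data. The C9A/C9B -> ACE_inhibitor rows are
# fixed by the phenotype definition and must be present.
cough:
  - {icd10: R05,   standard_name: chronic cough,                      category: CHRONIC}
  - {icd10: A16.9, standard_name: tuberculous cough,                  category: INFECTION}
  - {icd10: A37.0, standard_name: whooping cough caused by B. pertussis, category: INFECTION}
  - {icd10: A37.9, standard_name: whooping cough,                     category: INFECTION}
  - {icd10: R05,   standard_name: atopic cough,                       category: ATOPIC_ALLERGIC}
  - {icd10: R05,   standard_name: allergic cough,                     category: ATOPIC_ALLERGIC}
  - {icd10: J45.9, standard_name: cough-variant asthma,               category: CVA}
  - {icd10: R05,   standard_name: post-infectious cough,              category: POSTINFECTIOUS}
  - {icd10: F45.3, standard_name: psychogenic cough,                  category: OTHER}
  - {icd10: G44.8, standard_name: primary cough headache,             category: OTHER}
  - {icd10: R05,   standard_name: catarrhal cough,                    category: OTHER}
  - {icd10: R05,   standard_name: cough,                              category: OTHER}
  - {icd10: R05,   standard_name: syncope cough,                      category: OTHER}
  - {icd10: R05,   standard_name: dry cough,                          category: OTHER}
  - {icd10: R05,   standard_name: wet cough,                          category: OTHER}
  - {icd10: R05,   standard_name: prolonged subacute cough,           category: OTHER}
  - {icd10: R05,   standard_name: nocturnal cough,                    category: OTHER}
disease:
  - {prefix: J30,   label: ARNI}                      # allergic rhinitis / nasal inflammation
  - {prefix: J45,   label: asthma}
  - {prefix: K21,   label: GERD}
  - {prefix: J32,   label: paranasal_sinusitis}
  - {prefix: J44,   label: CAID}                      # chronic airway inflammatory disease
  - {prefix: J31.0, label: chronic_rhinitis}
  - {prefix: R09.8, label: postnasal_drip}
  - {prefix: J38.3, label: vocal_cord_dysfunction}
  - {prefix: J43,   label: emphysema}
  - {prefix: J33,   label: nasal_polyps}
  - {prefix: J84,   label: EXCL_organic_respiratory}  # interstitial lung disease
  - {prefix: E84,   label: EXCL_organic_respiratory}  # cystic fibrosis
  - {prefix: C,     label: EXCL_cancer}               # any malignancy chapter code
medication:
  - {prefix: R05D,  class: central_antitussive}
  - {prefix: R05C,  class: expectorant}
  - {prefix: R06A,  class: antiallergic}
  - {prefix: J01FA, class: antimicrobial_restricted}  # respiratory quinolones and 14-/15-member macrolides only
  - {prefix: J01MA, class: antimicrobial_restricted}
  - {prefix: R03AK, class: ICS_LABA}
  - {prefix: V90,   class: herbal}                    # synthetic leaf: kampo preparations carry no WHO ATC
  - {prefix: H02AB, class: corticosteroid}
  - {prefix: R03AC, class: bronchodilator_other}
  - {prefix: R03BB, class: bronchodilator_other}
  - {prefix: A02B,  class: peptic_ulcer}
  - {prefix: A03F,  class: GI_motility}
  - {prefix: C9A,   class: ACE_inhibitor}
  - {prefix: C9B,   class: ACE_inhibitor}
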