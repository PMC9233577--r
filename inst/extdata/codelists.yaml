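# Approximate, synthetic default code lists for the AGHD likelihood engine.
#
# The original study's full supplementary code lists are not publicly
# available. The entries below are clearly-versioned placeholders assembled
# from well-known terminology anchors (ATC drug-class prefixes, common ICD-10
# structural-lesion codes, routine endocrine-panel CPT codes) so that the
# whole pipeline is runnable and testable end to end. They are NOT a
# clinically validated phenotype definition: replace with a site-curated
# file for any real analysis. Every downstream report prints this version
# string so locally produced numbers are never mistaken for another
# configuration's.
version: "synthetic-defaults-0.1"

lists:
  # Structural/congenital conditions compatible with GHD when diagnosed at
  # any age. The source list also contained conditions that do not cause
  # complete GHD (e.g. unilateral cleft lip/palate) — retained in spirit.
  GROUP_A_CONDITIONS:
    - {system: ICD10CM, pattern: "D443", match_mode: prefix}   # craniopharyngioma / pituitary uncertain behavior
    - {system: ICD10CM, pattern: "D352", match_mode: prefix}   # benign pituitary neoplasm
    - {system: ICD10CM, pattern: "C751", match_mode: prefix}   # malignant pituitary neoplasm
    - {system: ICD10CM, pattern: "Q04", match_mode: prefix}    # congenital brain malformations
    - {system: ICD10CM, pattern: "Q37", match_mode: prefix}    # cleft palate with cleft lip
    - {system: ICD9CM, pattern: "2373", match_mode: prefix}    # pituitary neoplasm of uncertain behavior

  # Acquired insults that imply possible GHD only when diagnosed as an adult.
  GROUP_B_CONDITIONS:
    - {system: ICD10CM, pattern: "S06", match_mode: prefix}    # traumatic brain injury
    - {system: ICD10CM, pattern: "I60", match_mode: prefix}    # subarachnoid hemorrhage
    - {system: ICD10CM, pattern: "E236", match_mode: prefix}   # other pituitary disorders (incl. apoplexy)
    - {system: ICD9CM, pattern: "8540", match_mode: prefix}    # intracranial injury

  # Non-GH pituitary-axis deficiency diagnoses; the axis label is what the
  # >=3-deficiencies rule counts. The gh axis is listed for completeness but
  # is never counted (besides-GH rule).
  PITUITARY_DEFICIENCY_DX:
    - {system: ICD10CM, pattern: "E038", match_mode: prefix, axis: thyroid}   # central hypothyroidism (approx.)
    - {system: ICD9CM, pattern: "2448", match_mode: prefix, axis: thyroid}
    - {system: ICD10CM, pattern: "E274", match_mode: prefix, axis: adrenal}   # secondary adrenal insufficiency (approx.)
    - {system: ICD9CM, pattern: "2554", match_mode: prefix, axis: adrenal}
    - {system: ICD10CM, pattern: "E291", match_mode: prefix, axis: gonadal}   # hypogonadism, male
    - {system: ICD10CM, pattern: "E283", match_mode: prefix, axis: gonadal}   # ovarian failure
    - {system: ICD9CM, pattern: "2534", match_mode: prefix, axis: prolactin}  # other anterior pituitary disorder (placeholder)
    - {system: ICD10CM, pattern: "E232", match_mode: prefix, axis: posterior} # diabetes insipidus
    - {system: ICD9CM, pattern: "2535", match_mode: prefix, axis: posterior}
    - {system: ICD10CM, pattern: "E230", match_mode: prefix, axis: gh}        # hypopituitarism incl. GHD — never counted

  # Diagnoses that veto the two prescription-based high paths (conditions
  # that otherwise explain GH or multi-hormone use).
  EXCLUSION_1:
    - {system: ICD10CM, pattern: "Q96", match_mode: prefix}    # Turner syndrome
    - {system: ICD10CM, pattern: "E343", match_mode: prefix}   # short stature
    - {system: ICD10CM, pattern: "N18", match_mode: prefix}    # chronic kidney disease
  EXCLUSION_2:
    - {system: ICD10CM, pattern: "B20", match_mode: prefix}    # HIV disease (wasting indication)
    - {system: ICD10CM, pattern: "R64", match_mode: prefix}    # cachexia

  GH_THERAPY_RX:
    - {system: ATC, pattern: "H01AC", match_mode: prefix}      # somatropin and analogues

  # Replacement classes for the >=3-replacements-in-one-year rule; the axis
  # label is the "class" that gets counted.
  HORMONE_REPLACEMENT_RX:
    - {system: ATC, pattern: "G03", match_mode: prefix, axis: gonadal}   # sex hormones
    - {system: ATC, pattern: "H02AB", match_mode: prefix, axis: adrenal} # systemic glucocorticoids
    - {system: ATC, pattern: "H03AA", match_mode: prefix, axis: thyroid} # thyroid preparations

  # GHD-specific diagnostic tests; the label feeds the per-test usage table.
  GHD_TEST_CPT:
    - {system: CPT, pattern: "84305", match_mode: exact, label: igf1_serum}
    - {system: CPT, pattern: "83003", match_mode: exact, label: gh_serum}
    - {system: CPT, pattern: "80428", match_mode: exact, label: gh_stim_arginine_levodopa}
    - {system: CPT, pattern: "80422", match_mode: exact, label: gh_stim_glucagon}
    - {system: CPT, pattern: "80434", match_mode: exact, label: gh_stim_insulin_tolerance}

  # Non-GH pituitary-axis laboratory tests; >=3 distinct axes tested puts a
  # person in the moderate tier when no high path fired.
  AXIS_TEST_CPT:
    - {system: CPT, pattern: "84443", match_mode: exact, axis: thyroid}   # TSH
    - {system: CPT, pattern: "84439", match_mode: exact, axis: thyroid}   # free T4
    - {system: CPT, pattern: "82533", match_mode: exact, axis: adrenal}   # cortisol
    - {system: CPT, pattern: "82024", match_mode: exact, axis: adrenal}   # ACTH
    - {system: CPT, pattern: "83001", match_mode: exact, axis: gonadal}   # FSH
    - {system: CPT, pattern: "83002", match_mode: exact, axis: gonadal}   # LH
    - {system: CPT, pattern: "84146", match_mode: exact, axis: prolactin} # prolactin

# One diagnosis list per reported comorbidity (last-year incidence tables).
# Lists are kept pairwise disjoint so planted synthetic prevalences are
# independently recoverable; in particular breast cancer is its own list and
# is not folded into malignant_neoplastic_disease here.
comorbidities:
  hypertensive_disorder:
    - {system: ICD10CM, pattern: "I10", match_mode: prefix}
  hyperlipidemia:
    - {system: ICD10CM, pattern: "E78", match_mode: prefix}
  heart_disease:
    - {system: ICD10CM, pattern: "I25", match_mode: prefix}
    - {system: ICD10CM, pattern: "I50", match_mode: prefix}
  diabetes_or_impaired_glucose:
    - {system: ICD10CM, pattern: "E11", match_mode: prefix}
    - {system: ICD10CM, pattern: "R73", match_mode: prefix}
  osteoarthritis:
    - {system: ICD10CM, pattern: "M15", match_mode: prefix}
    - {system: ICD10CM, pattern: "M16", match_mode: prefix}
    - {system: ICD10CM, pattern: "M17", match_mode: prefix}
    - {system: ICD10CM, pattern: "M19", match_mode: prefix}
  malignant_neoplastic_disease:
    - {system: ICD10CM, pattern: "C18", match_mode: prefix}
    - {system: ICD10CM, pattern: "C34", match_mode: prefix}
    - {system: ICD10CM, pattern: "C61", match_mode: prefix}
    - {system: ICD10CM, pattern: "C67", match_mode: prefix}
    - {system: ICD10CM, pattern: "C82", match_mode: prefix}
  malignant_tumor_of_breast:
    - {system: ICD10CM, pattern: "C50", match_mode: prefix}
  depressive_disorder:
    - {system: ICD10CM, pattern: "F32", match_mode: prefix}
    - {system: ICD10CM, pattern: "F33", match_mode: prefix}
  visual_system_disorder:
    - {system: ICD10CM, pattern: "H40", match_mode: prefix}
    - {system: ICD10CM, pattern: "H25", match_mode: prefix}
  acute_respiratory_disease:
    - {system: ICD10CM, pattern: "J06", match_mode: prefix}
    - {system: ICD10CM, pattern: "J20", match_mode: prefix}
  cerebrovascular_disease:
    - {system: ICD10CM, pattern: "I63", match_mode: prefix}
    - {system: ICD10CM, pattern: "I65", match_mode: prefix}
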