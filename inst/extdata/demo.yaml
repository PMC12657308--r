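# Demonstration experiment: a validation-style cohort (12 % CKD
# prevalence) with informative pre-admission history, both HIB profiles.
simulation:
  n_patients: 400
  ckd_prevalence: 0.12
  seed: 20260101
  stays_per_patient_rate: 2.5
  labs_per_stay_rate: 4
  creatinine_noise_cv: 0.2
  aki_rate_nonckd: 0.25
  aki_rate_ckd: 0.2
cohort:
  profile: gold
  history_start: "2011-01-01"
model:
  profiles: [admissionHIB, historyHIB]
  split_fraction: 0.8
  seed: 20260101
evaluation:
  ci_level: 0.95
  bootstrap: 200
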