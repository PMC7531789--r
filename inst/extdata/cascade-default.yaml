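# Default triage cascade configuration -- RECONSTRUCTED DEFAULTS.
#
# The danger-sign list, the logistic admission-risk (IPSI) coefficients, the
# additive respiratory-severity (RISC) point values, and all numeric
# thresholds below are plausible ETAT/IMCI-flavoured reconstructions chosen
# for this implementation; they are NOT the values used at any particular
# hospital deployment. Every deployment should replace this file with its
# own calibrated cascade.
schema_version: 1
provenance: reconstructed defaults
danger_signs:
  - unconscious
  - convulsing
  - obvious_respiratory_distress
  - cyanosis
  - severe_trauma
  - suspected_neonatal_sepsis
symptoms:
  - cough
  - difficulty_breathing
  - diarrhea
  - vomiting
  - fever_history
  - inability_to_drink_or_eat
  - wheezing
  - convulsions_history
  - ear_discharge
  - skin_rash
  - poor_feeding
signs:
  - chest_indrawing
  - lethargy
  - irritability
  - pallor
  - dehydration
ipsi:
  min_age_months: 3
  priority_threshold: 0.15
  emergency_threshold: 0.50
  intercept: 0.0
  coefficients:
    age: -0.010            # per month
    temperature: 0.25      # per degree C
    respiratory_rate: 0.04 # per breath/min
    spo2: -0.15            # per percentage point
    cough: 0.30
    difficulty_breathing: 0.80
    chest_indrawing: 1.00
    lethargy: 1.20
    irritability: 0.60
    diarrhea: 0.40
risc:
  max_age_months: 24
  priority_threshold: 3
  emergency_threshold: 5
  applicability_any_of:    # "lower respiratory chest infection" indications
    - cough
    - difficulty_breathing
    - chest_indrawing
    - wheezing
  points:
    spo2_below: {threshold: 90, points: 3}
    chest_indrawing: 2
    wheezing: 1
    inability_to_drink_or_eat: 1
    low_weight:
      - {age_min: 0,  age_max: 2,  weight_below: 3.0, points: 2}
      - {age_min: 2,  age_max: 12, weight_below: 5.0, points: 2}
      - {age_min: 12, age_max: 24, weight_below: 7.0, points: 2}
    hiv: {positive: 2, unknown: 1, negative: 0}
vital_thresholds:
  spo2:
    - {age_min: 0, age_max: .inf, emergency_below: 87, priority_below: 92}
  respiratory_rate:
    - {age_min: 0,  age_max: 2,    emergency_above: 70, priority_above: 60}
    - {age_min: 2,  age_max: 12,   emergency_above: 65, priority_above: 50}
    - {age_min: 12, age_max: 60,   emergency_above: 55, priority_above: 40}
    - {age_min: 60, age_max: .inf, emergency_above: 40, priority_above: 30}
  heart_rate:
    - {age_min: 0,  age_max: 12,   emergency_above: 200, priority_above: 180}
    - {age_min: 12, age_max: 60,   emergency_above: 190, priority_above: 160}
    - {age_min: 60, age_max: .inf, emergency_above: 160, priority_above: 140}
  temperature:
    - {age_min: 0, age_max: .inf, emergency_below: 35.0, priority_above: 39.5}
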