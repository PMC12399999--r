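# Measles configuration.
# Vaccine and treatment efficacies are literature point estimates with 95%
# uncertainty intervals. Relative-risk magnitudes are ILLUSTRATIVE
# placeholders: the cited morbidity/mortality relative risks are not
# printed with the efficacy table, and real analyses must substitute
# study-specific values.
disease: measles
case_factors:
  - name: stunting
    levels: [none, moderate, severe]
    rr: [1.0, 1.6, 2.3]
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 1.8]
  - name: vitamin_a_deficiency
    levels: [none, deficient]
    rr: [1.0, 1.5]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 1.7, 2.6]
death_factors:
  - name: stunting
    levels: [none, moderate, severe]
    rr: [1.0, 2.0, 3.0]
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 2.1]
  - name: vitamin_a_deficiency
    levels: [none, deficient]
    rr: [1.0, 1.9]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 2.2, 3.4]
vaccines:
  - name: measles
    efficacy: 0.85
    ui: [0.83, 0.87]
    attributable_fraction: 1.0
treatment:
  efficacy: 0.62
  ui: [0.52, 0.82]
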