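# Pneumonia configuration.
# Pneumococcal conjugate vaccine covers the 33.0% of pneumonia cases
# attributable to pneumococcus; the Hib component of the pentavalent
# vaccine covers the 21.6% attributable to Haemophilus influenzae type b.
# Relative-risk magnitudes are ILLUSTRATIVE placeholders (see measles.yaml).
disease: pneumonia
case_factors:
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 1.9]
  - name: vitamin_a_deficiency
    levels: [none, deficient]
    rr: [1.0, 1.4]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 1.8, 2.9]
death_factors:
  - name: stunting
    levels: [none, moderate, severe]
    rr: [1.0, 1.9, 2.9]
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 2.2]
  - name: vitamin_a_deficiency
    levels: [none, deficient]
    rr: [1.0, 1.8]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 2.3, 3.8]
vaccines:
  - name: pcv
    efficacy: 0.58
    ui: [0.29, 0.75]
    attributable_fraction: 0.330
  - name: hib
    efficacy: 0.93
    ui: [0.83, 0.97]
    attributable_fraction: 0.216
treatment:
  efficacy: 0.70
  ui: [0.52, 0.82]
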