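# Diarrhoea configuration.
# The rotavirus vaccine acts on the rotavirus-attributable share of
# diarrhoea cases; the attributable fraction here (0.28) is an ILLUSTRATIVE
# placeholder, as are all relative-risk magnitudes (see measles.yaml).
disease: diarrhoea
case_factors:
  - name: stunting
    levels: [none, moderate, severe]
    rr: [1.0, 1.6, 2.3]
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 1.7]
  - name: unsafe_sanitation
    levels: [improved, unimproved]
    rr: [1.0, 1.4]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 1.8, 2.8]
death_factors:
  - name: stunting
    levels: [none, moderate, severe]
    rr: [1.0, 2.0, 3.2]
  - name: underweight
    levels: [none, underweight]
    rr: [1.0, 2.0]
  - name: wasting
    levels: [none, moderate, severe]
    rr: [1.0, 2.2, 3.6]
vaccines:
  - name: rotavirus
    efficacy: 0.50
    ui: [0.11, 0.72]
    attributable_fraction: 0.28
treatment:
  efficacy: 0.93
  ui: [0.83, 0.98]
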